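## Conserved-residue validation, motif / indel / extension calling and
## clade assignment for candidate NirK proteins, all in reference
## residue numbering.

#' Conserved residue rules for NirK validation
#'
#' The seven copper-ligand positions (His59, His64, His99, Cys100, His110,
#' Met115, His298; T1Cu and T2Cu centres) and the two active-site residues
#' (Asp62, His237) that a functional copper nitrite reductase must carry.
#' All nine rules are treated equally by validation; the T1Cu/T2Cu
#' partition is not used.  `allowed` may list alternatives separated by
#' `|`; `X` never satisfies a rule.
#'
#' @return `data.frame` with columns `position`, `allowed`, `role`.
#' @export
defaultResidueRules <- function() {
  r <- data.frame(
    position = c(59L, 62L, 64L, 99L, 100L, 110L, 115L, 237L, 298L),
    allowed  = c("H", "D", "H", "H", "C", "H", "M", "H", "H"),
    role     = c("Cu_ligand", "active_site", "Cu_ligand", "Cu_ligand",
                 "Cu_ligand", "Cu_ligand", "Cu_ligand", "active_site",
                 "Cu_ligand"),
    stringsAsFactors = FALSE)
  validateRuleSet(r)
  r
}

validateRuleSet <- function(rules, ref_length = 375L) {
  stopifnot(is.data.frame(rules),
            all(c("position", "allowed", "role") %in% names(rules)))
  if (is.unsorted(rules$position, strictly = TRUE))
    stop("rule positions must be strictly increasing")
  if (any(rules$position < 1L | rules$position > ref_length))
    stop("rule position outside reference length ", ref_length)
  if (any(!nzchar(rules$allowed)))
    stop("allowed residue sets must be non-empty")
  invisible(rules)
}

#' Validate a candidate against the conserved-residue rules
#'
#' A sequence is accepted as NirK iff every rule passes.  A reference
#' position that is deleted in the target (or only reachable as `X`)
#' fails its rule.
#'
#' @param target Protein string or single-sequence [NirKSet-class].
#' @param map [ReferenceMap-class] of `target` against the reference the
#'   rules are numbered on.
#' @param rules See [defaultResidueRules()].
#' @return List with `report` (`data.frame`: position, role, allowed,
#'   observed, pass) and `is_nirk` (all rules pass).
#' @export
validateResidues <- function(target, map, rules = defaultResidueRules()) {
  validateRuleSet(rules, ref_length = length(map@ref_to_target))
  obs <- residueAt(map, target, rules$position)
  allowed <- strsplit(rules$allowed, "|", fixed = TRUE)
  pass <- mapply(function(o, a) o != "deleted" && o != "X" && o %in% a,
                 obs, allowed)
  report <- data.frame(position = rules$position, role = rules$role,
                       allowed = rules$allowed, observed = obs,
                       pass = unname(pass), stringsAsFactors = FALSE,
                       row.names = NULL)
  list(report = report, is_nirk = all(pass))
}

#' Extract the active-site motifs around His237 and Asp62
#'
#' The His237 motif is the 5-mer at reference positions 234-238 (window
#' -3..+1 around the active-site His, matching the published TRPHL /
#' SSFHV-type motifs where the His is fourth of five).  The Asp62 motif is
#' the symmetric 5-mer at 60-64.  A window touching a deleted position
#' yields an undefined (flagged) motif.
#'
#' @inheritParams validateResidues
#' @param his_center,asp_center Reference positions of the two active-site
#'   residues.
#' @param his_window,asp_window Offsets (lo, hi) around each centre.
#' @return List: `his237_motif`, `asp62_motif` (NA when undefined),
#'   `his237_defined`, `asp62_defined`.
#' @export
extractMotifs <- function(target, map, his_center = 237L,
                          asp_center = 62L, his_window = c(-3L, 1L),
                          asp_window = c(-2L, 2L)) {
  one <- function(center, win) {
    pos <- (center + win[1]):(center + win[2])
    res <- residueAt(map, target, pos)
    if (any(res == "deleted")) list(motif = NA_character_, defined = FALSE)
    else list(motif = paste(res, collapse = ""), defined = TRUE)
  }
  h <- one(his_center, his_window)
  a <- one(asp_center, asp_window)
  list(his237_motif = h$motif, asp62_motif = a$motif,
       his237_defined = h$defined, asp62_defined = a$defined)
}

#' Clade-diagnostic indel regions
#'
#' The two 7-aa deletion regions diagnostic of Clade II coincide with the
#' linker and tower loop.  Their reference coordinates are not fixed by
#' structure alone and are configuration values shared with the synthetic
#' generator (defaults: linker 190-196, tower 258-264 in surrogate
#' coordinates).  The Bacillaceae-specific extra loop is modelled as an
#' insertion between reference positions 310 and 311.
#'
#' @return `data.frame` with columns `label`, `start`, `end`, `kind`,
#'   `expected_length`.
#' @export
defaultIndelRegions <- function() {
  data.frame(
    label = c("linker", "tower", "bacillus_loop"),
    start = c(190L, 258L, 310L),
    end   = c(196L, 264L, 311L),
    kind  = c("deletion", "deletion", "insertion"),
    expected_length = c(7L, 7L, 10L),
    stringsAsFactors = FALSE)
}

#' Call clade-diagnostic indels
#'
#' A deletion region is called present when the majority of its reference
#' positions — at least `ceiling(L/2) + 1` of the `L` expected — are
#' deleted in the target; this tolerates ragged gap edges from point
#' indels while remaining specific.  `observed_length` is the count of
#' deleted positions in the interval.  For insertion regions the number
#' of target residues inserted strictly between the interval's flanking
#' reference positions is counted, with the same majority threshold on
#' `expected_length`.
#'
#' @inheritParams validateResidues
#' @param regions See [defaultIndelRegions()].
#' @return `data.frame`: `label`, `kind`, `start`, `end`,
#'   `expected_length`, `observed_length`, `present`.
#' @export
detectIndels <- function(target, map, regions = defaultIndelRegions()) {
  nref <- length(map@ref_to_target)
  stopifnot(all(regions$start >= 1L), all(regions$end <= nref),
            all(regions$start <= regions$end))
  prev <- cummaxNA(map@target_to_ref)
  t2r <- map@target_to_ref
  interior <- seq_along(t2r) > map@n_term_overhang &
    seq_along(t2r) <= length(t2r) - map@c_term_overhang
  obs <- integer(nrow(regions))
  for (k in seq_len(nrow(regions))) {
    if (regions$kind[k] == "deletion") {
      obs[k] <- sum(is.na(map@ref_to_target[regions$start[k]:regions$end[k]]))
    } else {
      obs[k] <- sum(interior & is.na(t2r) &
                      prev >= regions$start[k] & prev < regions$end[k])
    }
  }
  thr <- ceiling(regions$expected_length / 2) + 1L
  data.frame(label = regions$label, kind = regions$kind,
             start = regions$start, end = regions$end,
             expected_length = regions$expected_length,
             observed_length = obs, present = obs >= thr,
             stringsAsFactors = FALSE)
}

#' Domain-extension patterns
#'
#' Spaced-residue templates for the two known NirK terminal extensions:
#' the class I c-type heme domain `C-x2-C-H-x50-M` searched in the
#' C-terminal overhang, and the cupredoxin domain `C-x4-H-x4-M` searched
#' in the N-terminal overhang.  Spacer lengths are matched exactly by
#' default (`spacer_tolerance = 0`), as the templates specify exact
#' counts; a tolerance can be set for noisy real data.
#'
#' @param spacer_tolerance Allowed +/- slack on every spacer length.
#' @return Named list of pattern descriptions.
#' @export
defaultDomainPatterns <- function(spacer_tolerance = 0L) {
  list(
    heme_c = list(name = "heme_c", anchors = c("C", "C", "H", "M"),
                  spacers = c(2L, 0L, 50L), zone = "c_term_overhang",
                  tolerance = spacer_tolerance),
    cupredoxin = list(name = "cupredoxin", anchors = c("C", "H", "M"),
                      spacers = c(4L, 4L), zone = "n_term_overhang",
                      tolerance = spacer_tolerance))
}

patternRegex <- function(p) {
  t <- p$tolerance
  parts <- p$anchors[1]
  for (k in seq_along(p$spacers))
    parts <- c(parts,
               sprintf(".{%d,%d}", max(0L, p$spacers[k] - t),
                       p$spacers[k] + t),
               p$anchors[k + 1])
  paste(parts, collapse = "")
}

#' Detect N-/C-terminal domain extensions
#'
#' Scans only the declared overhang zone of the target (the residues the
#' reference map classifies as terminal overhang), never the mapped
#' reference span, and reports the 1-based offset of the first match
#' within the overhang.
#'
#' @inheritParams validateResidues
#' @param patterns See [defaultDomainPatterns()].
#' @return List: `n_overhang_len`, `c_overhang_len`, and per pattern
#'   `<name>_found` / `<name>_offset`.
#' @export
detectExtensions <- function(target, map,
                             patterns = defaultDomainPatterns()) {
  if (is(target, "NirKSet")) target <- unname(sequences(target))[1L]
  n <- nchar(target)
  zones <- list(
    n_term_overhang = substr(target, 1L, map@n_term_overhang),
    c_term_overhang = substr(target, n - map@c_term_overhang + 1L, n))
  if (map@n_term_overhang == 0L) zones$n_term_overhang <- ""
  if (map@c_term_overhang == 0L) zones$c_term_overhang <- ""
  out <- list(n_overhang_len = map@n_term_overhang,
              c_overhang_len = map@c_term_overhang)
  for (p in patterns) {
    hit <- regexpr(patternRegex(p), zones[[p$zone]], perl = TRUE)
    out[[paste0(p$name, "_found")]] <- hit > 0L
    out[[paste0(p$name, "_offset")]] <-
      if (hit > 0L) as.integer(hit) else NA_integer_
  }
  out
}

#' Assign a sequence to a NirK clade from its indel calls
#'
#' Both clade-diagnostic deletions (linker and tower) present implies
#' Clade II; neither implies Clade I; exactly one yields
#' `"unclassified"` — the literature gives no rule for that case and we
#' prefer an explicit fallback over a guess.
#'
#' @param indel_calls `data.frame` from [detectIndels()].
#' @return `"I"`, `"II"` or `"unclassified"`.
#' @export
assignClade <- function(indel_calls) {
  del <- indel_calls[indel_calls$kind == "deletion" &
                       indel_calls$label %in% c("linker", "tower"), ]
  stopifnot(nrow(del) == 2L)
  n <- sum(del$present)
  if (n == 2L) "II" else if (n == 0L) "I" else "unclassified"
}

#' Profile every sequence of a set
#'
#' Runs the full per-sequence pipeline — reference mapping, residue
#' validation, motif extraction, indel calling, extension detection and
#' clade assignment — over a protein [NirKSet-class].
#'
#' @param set Protein [NirKSet-class].
#' @param ref Reference (see [surrogateReference()]).
#' @param scoring,rules,regions,patterns Stage parameters; see
#'   [alignScoring()], [defaultResidueRules()], [defaultIndelRegions()],
#'   [defaultDomainPatterns()].
#' @return List with `profiles` (one `data.frame` row per sequence),
#'   `maps` (named list of [ReferenceMap-class]) and `residue_reports`
#'   (named list of per-rule verdicts).
#' @export
classifySequences <- function(set, ref = surrogateReference(),
                              scoring = alignScoring(),
                              rules = defaultResidueRules(),
                              regions = defaultIndelRegions(),
                              patterns = defaultDomainPatterns()) {
  stopifnot(is(set, "NirKSet"), set@alphabet == "protein")
  seqs <- sequences(set)
  maps <- list()
  reports <- list()
  rows <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    id <- names(seqs)[k]
    s <- unname(seqs[k])
    map <- mapToReference(s, ref, scoring, id = id)
    val <- validateResidues(s, map, rules)
    mot <- extractMotifs(s, map)
    ind <- detectIndels(s, map, regions)
    ext <- detectExtensions(s, map, patterns)
    gl <- function(lab, col) {
      i <- which(ind$label == lab)
      if (length(i)) ind[[col]][i] else NA
    }
    rows[[k]] <- data.frame(
      id = id, length = nchar(s), is_nirk = val$is_nirk,
      n_rules_passed = sum(val$report$pass),
      his237_motif = mot$his237_motif, asp62_motif = mot$asp62_motif,
      linker_deleted = isTRUE(gl("linker", "present")),
      tower_deleted = isTRUE(gl("tower", "present")),
      linker_len = gl("linker", "observed_length"),
      tower_len = gl("tower", "observed_length"),
      bacillus_loop = isTRUE(gl("bacillus_loop", "present")),
      clade = assignClade(ind),
      n_overhang = ext$n_overhang_len, c_overhang = ext$c_overhang_len,
      heme_c = ext$heme_c_found, cupredoxin = ext$cupredoxin_found,
      align_score = map@score, stringsAsFactors = FALSE)
    maps[[id]] <- map
    reports[[id]] <- val$report
  }
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  list(profiles = profiles, maps = maps, residue_reports = reports)
}

#' Write sequence profiles to TSV or JSON
#'
#' @param profiles `data.frame` from [classifySequences()].
#' @param path Output path; format chosen by `format`.
#' @param format `"tsv"` or `"json"`.
#' @export
writeProfiles <- function(profiles, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    write.table(profiles, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  else
    jsonlite::write_json(profiles, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Remove redundant same-species duplicates
#'
#' Among records with identical residues and identical species, only the
#' lexicographically smallest id is kept (different strains of the same
#' species with identical sequences add no information); identical
#' sequences from different species, or same-species sequences that differ
#' anywhere, are all retained.
#'
#' @param set A [NirKSet-class] with species metadata.
#' @return List with `set` (retained records) and `removed` (`data.frame`
#'   of dropped ids and the id each duplicates).
#' @export
filterRedundant <- function(set) {
  stopifnot(is(set, "NirKSet"))
  m <- seqMeta(set)
  if (anyNA(m$species)) stop("species metadata required for all records")
  key <- paste(m$species, sequences(set), sep = "\r")
  keep <- rep(TRUE, length(set))
  removed <- list()
  for (g in split(seq_along(key), key)) {
    if (length(g) > 1L) {
      ids <- m$id[g]
      drop <- g[ids != min(ids)]
      keep[drop] <- FALSE
      removed[[length(removed) + 1L]] <-
        data.frame(id = m$id[drop], duplicate_of = min(ids),
                   species = m$species[drop], stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed)
  else data.frame(id = character(), duplicate_of = character(),
                  species = character(), stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  list(set = set[which(keep)], removed = removed)
}

#' Mean pairwise percent identity, per group and overall
#'
#' Pairwise identity between two aligned rows is the number of identical
#' columns divided by the number of columns where neither row is gapped
#' (pairwise deletion), times 100.  Group values are means over unordered
#' within-group pairs; groups of size < 2 are flagged undefined.
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param grouping Named character vector mapping row names to group labels.
#' @return List with `groups` (`data.frame`: group, n, mean_identity,
#'   defined) and `overall` (mean over all pairs).
#' @export
groupSimilarity <- function(aln, grouping = NULL) {
  stopifnot(length(aln) >= 2L, length(unique(nchar(aln))) == 1L)
  ids <- names(aln)
  mat <- do.call(rbind, strsplit(aln, ""))
  pid <- function(i, j) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) return(NA_real_)
    100 * sum(a[ok] == b[ok]) / sum(ok)
  }
  prs <- combn(length(aln), 2L)
  vals <- mapply(pid, prs[1, ], prs[2, ])
  overall <- mean(vals, na.rm = TRUE)
  groups <- NULL
  if (!is.null(grouping)) {
    glab <- grouping[ids]
    gs <- lapply(split(seq_along(ids), glab), function(g) {
      if (length(g) < 2L)
        return(data.frame(n = length(g), mean_identity = NA_real_,
                          defined = FALSE))
      p <- combn(g, 2L)
      data.frame(n = length(g),
                 mean_identity = mean(mapply(pid, p[1, ], p[2, ]),
                                      na.rm = TRUE),
                 defined = TRUE)
    })
    groups <- cbind(data.frame(group = names(gs), stringsAsFactors = FALSE),
                    do.call(rbind, gs))
    rownames(groups) <- NULL
  }
  list(groups = groups, overall = overall)
}

#' Per-genome nirK copy counts
#'
#' @param ids Sequence ids.
#' @param genome_of Named character vector mapping every id to a genome id.
#' @return List with `counts` (named integer vector per genome) and
#'   `multi_copy_fraction` (fraction of genomes with >= 2 copies).
#' @export
countCopies <- function(ids, genome_of) {
  if (any(!ids %in% names(genome_of)))
    stop("genome mapping must cover every sequence id")
  tab <- table(unname(genome_of[ids]))
  counts <- setNames(as.integer(tab), names(tab))
  list(counts = counts,
       multi_copy_fraction = mean(counts >= 2L))
}
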
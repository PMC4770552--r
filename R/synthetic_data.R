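## Seeded synthetic-data generators: NirK protein sets with planted
## clade structure (diagnostic deletions, active-site motifs, terminal
## extensions, multi-copy genomes), nucleotide back-translations with
## planted primer binding sites, and genome gene inventories with
## specified presence frequencies and pairwise odds-ratio associations.
## All generators are pure functions of (config, seed) and return a
## ground-truth table alongside the data.

#' Configuration for the NirK sequence generator
#'
#' Defaults define the study conditions used throughout the package's
#' tests: ten sequences per clade, no substitution noise, extension
#' fractions matching the roughly 30 % incidence of terminal extensions
#' (split evenly between the c-type heme and cupredoxin types), and a 5 %
#' multi-copy genome fraction.
#'
#' @param n_clade1,n_clade2,n_bacillus_loop Sequence counts; the
#'   Bacillus-type sequences are Clade II sequences carrying the extra
#'   loop insertion.
#' @param substitution_rate Per-position substitution probability in
#'   `[0, 1)`, applied outside protected positions (residue rules, motif
#'   windows, indel regions plus 3-residue flanks).
#' @param indel_regions See [defaultIndelRegions()]; shared with the
#'   feature caller.
#' @param fraction_with_heme_ext,fraction_with_cupredoxin_ext Fractions of
#'   sequences receiving a C-terminal heme / N-terminal cupredoxin
#'   extension (a sequence never receives both).
#' @param multi_copy_fraction Probability that a genome carries two nirK
#'   copies.
#' @param seed Integer seed.
#' @return A validated config list.
#' @export
seqGenConfig <- function(n_clade1 = 10L, n_clade2 = 10L,
                         n_bacillus_loop = 0L, substitution_rate = 0,
                         indel_regions = defaultIndelRegions(),
                         fraction_with_heme_ext = 0.15,
                         fraction_with_cupredoxin_ext = 0.15,
                         multi_copy_fraction = 0.05, seed = 1L) {
  cfg <- list(n_clade1 = as.integer(n_clade1),
              n_clade2 = as.integer(n_clade2),
              n_bacillus_loop = as.integer(n_bacillus_loop),
              substitution_rate = substitution_rate,
              indel_regions = indel_regions,
              fraction_with_heme_ext = fraction_with_heme_ext,
              fraction_with_cupredoxin_ext = fraction_with_cupredoxin_ext,
              multi_copy_fraction = multi_copy_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_clade1 >= 0L, n_clade2 >= 0L, n_bacillus_loop >= 0L,
              multi_copy_fraction >= 0, multi_copy_fraction <= 1,
              fraction_with_heme_ext >= 0, fraction_with_cupredoxin_ext >= 0,
              fraction_with_heme_ext + fraction_with_cupredoxin_ext <= 1)
    if (substitution_rate < 0 || substitution_rate >= 1)
      stop("substitution_rate must be in [0, 1)")
  })
  # deletion regions must not overlap the constrained positions
  prot <- c(defaultResidueRules()$position, 60:64, 234:238)
  del <- cfg$indel_regions[cfg$indel_regions$kind == "deletion", ]
  for (k in seq_len(nrow(del)))
    if (any(prot >= del$start[k] & prot <= del$end[k]))
      stop("indel region '", del$label[k],
           "' overlaps protected residue positions")
  cfg
}

# positions never touched by substitution noise; the termini stay fixed
# so that terminal extensions always map as overhangs
protectedPositions <- function(cfg) {
  prot <- c(1L, 375L, defaultResidueRules()$position, 60:64, 234:238)
  for (k in seq_len(nrow(cfg$indel_regions))) {
    r <- cfg$indel_regions[k, ]
    prot <- c(prot, max(1L, r$start - 3L):min(375L, r$end + 3L))
  }
  sort(unique(prot))
}

CLADE1_PHYLA <- c("Alphaproteobacteria", "Betaproteobacteria",
                  "Gammaproteobacteria")
CLADE2_PHYLA <- c("Bacteroidetes", "Actinobacteria", "Euryarchaeota",
                  "Chloroflexi", "Betaproteobacteria",
                  "Gammaproteobacteria", "Firmicutes")

#' Generate a synthetic NirK sequence set with ground truth
#'
#' Clade I sequences are derived from the 375-aa surrogate reference
#' (TRPHL active-site motif); Clade II sequences carry the SSFHV motif
#' and both 7-aa clade-diagnostic deletions (linker, tower); Bacillus-type
#' sequences additionally carry the extra loop insertion.  Substitutions
#' are applied i.i.d. outside protected positions; terminal extensions
#' with exact `C-x2-C-H-x50-M` / `C-x4-H-x4-M` spacing are appended per
#' the configured fractions; sequences are grouped into genomes with the
#' configured multi-copy fraction.  Fully reproducible under the config
#' seed.
#'
#' @param cfg See [seqGenConfig()].
#' @return List: `set` (protein [NirKSet-class]), `truth` (`data.frame`,
#'   one row per sequence), `reference` (the surrogate reference set).
#' @export
generateNirkSet <- function(cfg = seqGenConfig()) {
  ref <- surrogateReference()
  refres <- strsplit(unname(sequences(ref))[1L], "")[[1]]
  aa20 <- setdiff(ALPHABETS$protein, "X")
  prot <- protectedPositions(cfg)
  regions <- cfg$indel_regions
  del <- regions[regions$kind == "deletion", ]
  ins <- regions[regions$kind == "insertion" &
                   regions$label == "bacillus_loop", ]
  n_tot <- cfg$n_clade1 + cfg$n_clade2 + cfg$n_bacillus_loop
  stopifnot(n_tot >= 1L)
  clades <- c(rep("I", cfg$n_clade1), rep("II", cfg$n_clade2),
              rep("II", cfg$n_bacillus_loop))
  bacillus <- c(rep(FALSE, cfg$n_clade1 + cfg$n_clade2),
                rep(TRUE, cfg$n_bacillus_loop))

  withSeed(cfg$seed, {
    # extension assignment: at most one per sequence
    u <- runif(n_tot)
    ext <- ifelse(u < cfg$fraction_with_heme_ext, "heme",
                  ifelse(u < cfg$fraction_with_heme_ext +
                           cfg$fraction_with_cupredoxin_ext,
                         "cupredoxin", "none"))
    rows <- vector("list", n_tot)
    for (k in seq_len(n_tot)) {
      r <- refres
      if (clades[k] == "II") r[234:238] <- strsplit("SSFHV", "")[[1]]
      # substitution noise outside protected positions
      if (cfg$substitution_rate > 0) {
        hit <- which(runif(375L) < cfg$substitution_rate)
        hit <- setdiff(hit, prot)
        for (p in hit) r[p] <- sample(setdiff(aa20, r[p]), 1L)
      }
      ins_loop <- ""
      if (bacillus[k])
        ins_loop <- paste(sample(aa20, ins$expected_length[1],
                                 replace = TRUE), collapse = "")
      drop <- integer(0)
      if (clades[k] == "II")
        for (d in seq_len(nrow(del)))
          drop <- c(drop, del$start[d]:del$end[d])
      core <- character(0)
      for (p in seq_len(375L)) {
        if (!p %in% drop) core <- c(core, r[p])
        if (bacillus[k] && p == ins$start[1]) core <- c(core, ins_loop)
      }
      s <- paste(core, collapse = "")
      # extensions start/end on their anchor residues: a stray terminal
      # residue matching the reference terminus would otherwise let the
      # aligner absorb it and misclassify the extension as an insertion
      if (ext[k] == "heme") {
        s <- paste0(s, sample(aa20, 1), "C",
                    paste(sample(aa20, 2, replace = TRUE), collapse = ""),
                    "CH",
                    paste(sample(aa20, 50, replace = TRUE), collapse = ""),
                    "M")
      } else if (ext[k] == "cupredoxin") {
        s <- paste0("C",
                    paste(sample(aa20, 4, replace = TRUE), collapse = ""),
                    "H",
                    paste(sample(aa20, 4, replace = TRUE), collapse = ""),
                    "M", sample(aa20, 1), s)
      }
      rows[[k]] <- s
    }
    # genome assignment with the configured multi-copy fraction, per clade
    genome <- character(n_tot)
    copy_index <- integer(n_tot)
    g <- 0L
    k <- 1L
    while (k <= n_tot) {
      g <- g + 1L
      two <- runif(1) < cfg$multi_copy_fraction && k < n_tot &&
        clades[k + 1L] == clades[k]
      size <- if (two) 2L else 1L
      for (cc in seq_len(size)) {
        genome[k] <- sprintf("G%03d", g)
        copy_index[k] <- cc
        k <- k + 1L
      }
    }
    phy_by_genome <- vapply(unique(genome), function(gg) {
      cl <- clades[genome == gg][1]
      if (bacillus[genome == gg][1]) "Firmicutes"
      else if (cl == "I") sample(CLADE1_PHYLA, 1L, prob = c(0.7, 0.15, 0.15))
      else sample(CLADE2_PHYLA, 1L)
    }, "")
    ids <- sprintf("synthNirK_%03d", seq_len(n_tot))
    meta <- data.frame(
      id = ids,
      species = sprintf("Synthetospira clade%s_%s", clades,
                        sub("^G", "", genome)),
      strain = sprintf("strain%d", copy_index),
      phylum = unname(phy_by_genome[genome]),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      id = ids, clade = clades, bacillus_loop = bacillus,
      his237_motif = ifelse(clades == "I", "TRPHL", "SSFHV"),
      asp62_motif = "VEDAH",
      linker_deleted = clades == "II", tower_deleted = clades == "II",
      extension = ext, genome_id = genome, copy_index = copy_index,
      phylum = meta$phylum, species = meta$species,
      stringsAsFactors = FALSE)
    set <- nirkSet(setNames(unlist(rows), ids), "protein", meta,
                   source = "synthetic")
    list(set = set, truth = truth, reference = ref)
  })
}

#' Back-translate proteins to nucleotide coding sequences
#'
#' Each amino acid is mapped to a uniformly chosen synonymous codon of the
#' standard genetic code; translating the result reproduces the input.
#'
#' @param set Protein [NirKSet-class] (no `X` residues).
#' @param seed Integer seed.
#' @return Nucleotide [NirKSet-class] with the same ids and metadata.
#' @export
backtranslate <- function(set, seed = 1L) {
  stopifnot(is(set, "NirKSet"), set@alphabet == "protein")
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  by_aa[["*"]] <- NULL
  seqs <- sequences(set)
  nt <- withSeed(seed, vapply(seqs, function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, names(by_aa))
    if (length(bad))
      stop("cannot back-translate residue(s): ",
           paste(unique(bad), collapse = ", "))
    paste(vapply(aa, function(a) {
      cods <- by_aa[[a]]
      if (length(cods) == 1L) cods else sample(cods, 1L)
    }, ""), collapse = "")
  }, ""))
  nirkSet(setNames(unname(nt), names(seqs)), "nucleotide", seqMeta(set),
          source = "synthetic")
}

#' Plant primer binding sites with controlled mismatches
#'
#' Embeds one binding site per record: a concrete realisation of the
#' degenerate primer, with mismatches introduced independently per primer
#' position at the per-group probabilities given in `mismatch_spec`.  For
#' reverse primers the site is written on the given strand as the reverse
#' complement, so that [bestBindingSite()] finds it on the scanned strand.
#'
#' @param set Nucleotide [NirKSet-class].
#' @param primer A [Primer-class].
#' @param mismatch_spec Named list: per group label, a numeric vector of
#'   per-position mismatch probabilities of length `nchar(primer)` (or a
#'   single number recycled).  Groups not listed get zero everywhere.
#' @param group_of Named character vector id -> group label.
#' @param site_start 1-based start of the planted site on the given
#'   strand; `NULL` draws one uniformly per record.
#' @param seed Integer seed.
#' @return List: `set` (modified records) and `truth` (`data.frame`: id,
#'   group, site_start on the given strand, scan_start on the scanned
#'   strand, planted mismatch positions in primer coordinates).
#' @export
plantPrimerSites <- function(set, primer, mismatch_spec, group_of,
                             site_start = NULL, seed = 1L) {
  stopifnot(is(set, "NirKSet"), set@alphabet == "nucleotide")
  L <- nchar(primer@sequence)
  psym <- strsplit(primer@sequence, "")[[1]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  bases <- c("A", "C", "G", "T")
  fully_degenerate <- psym == "N"  # no incompatible base exists
  spec <- lapply(mismatch_spec, function(v) {
    if (length(v) == 1L) {
      v <- rep(v, L)
      v[fully_degenerate] <- 0  # scalar rates skip N positions
    }
    if (length(v) != L)
      stop("mismatch spec length must equal primer length (", L, ")")
    stopifnot(all(v >= 0), all(v <= 1))
    if (any(v > 0 & fully_degenerate))
      stop("cannot plant a mismatch against 'N' at primer position(s) ",
           paste(which(v > 0 & fully_degenerate), collapse = ", "))
    v
  })
  seqs <- sequences(set)
  withSeed(seed, {
    rows <- vector("list", length(seqs))
    out <- seqs
    for (k in seq_along(seqs)) {
      id <- names(seqs)[k]
      g <- group_of[[id]]
      pv <- if (!is.null(spec[[g]])) spec[[g]] else rep(0, L)
      # concrete site: compatible base per position, then planted mismatches
      site <- vapply(seq_len(L), function(i)
        sample(sets[[psym[i]]], 1L)[[1]], "")
      mispos <- which(runif(L) < pv)
      for (i in mispos) {
        incompatible <- setdiff(bases, sets[[psym[i]]])
        if (!length(incompatible))
          stop("cannot plant a mismatch against 'N' at primer position ", i)
        site[i] <- sample(incompatible, 1L)
      }
      site_str <- paste(site, collapse = "")
      if (primer@orientation == "reverse") site_str <- revcompIupac(site_str)
      s <- unname(seqs[k])
      n <- nchar(s)
      if (n < L) stop("record '", id, "' shorter than primer")
      st <- if (is.null(site_start)) sample.int(n - L + 1L, 1L)
      else site_start
      stopifnot(st >= 1L, st + L - 1L <= n)
      substr(s, st, st + L - 1L) <- site_str
      out[k] <- s
      scan_start <- if (primer@orientation == "reverse")
        n - (st + L - 1L) + 1L else st
      rows[[k]] <- data.frame(
        id = id, group = g, site_start = st, scan_start = scan_start,
        n_mismatches = length(mispos),
        mismatch_positions = paste(mispos, collapse = ","),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(set = nirkSet(out, "nucleotide", seqMeta(set),
                       source = "synthetic"),
         truth = truth)
  })
}

#' Generate a genome inventory table with planted associations
#'
#' Gene presence is sampled per genome from the given frequencies;
#' gene pairs with a specified odds ratio are sampled from the exact 2x2
#' joint distribution solving (p1, p2, OR), propagated over the
#' association graph, which must be a forest (no cyclic constraints).
#' All genomes carry nirK (copies >= 1).
#'
#' @param n_per_phylum Named integer vector: genomes per phylum.
#' @param gene_freqs Named numeric vector of presence probabilities for
#'   the genes (defaults cover nirS, nor, nosZ, napA, narG, nrfA, nirB,
#'   nirV at frequencies typical of NirK-containing genomes).
#' @param associations List of `list(genes = c(a, b), or = psi)` entries.
#' @param multi_copy_fraction Probability of a second nirK copy.
#' @param seed Integer seed.
#' @return List: `inventory` (`data.frame`) and `truth` (the sampled
#'   parameters, including the solved joint for each association).
#' @export
generateInventory <- function(n_per_phylum = c(synthetic_phylum = 250L),
                              gene_freqs = defaultGeneFreqs(),
                              associations = list(
                                list(genes = c("narG", "nrfA"), or = 0.2)),
                              multi_copy_fraction = 0.05, seed = 1L) {
  stopifnot(all(n_per_phylum >= 0), all(gene_freqs >= 0),
            all(gene_freqs <= 1))
  genes <- names(gene_freqs)
  edges <- lapply(associations, function(a) {
    stopifnot(length(a$genes) == 2L, a$or > 0,
              all(a$genes %in% genes))
    a
  })
  # forest check: union-find over association edges
  parent <- setNames(genes, genes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in edges) {
    r1 <- find(e$genes[1]); r2 <- find(e$genes[2])
    if (r1 == r2)
      stop("association constraints must form a forest (cycle through '",
           e$genes[1], "'-'", e$genes[2], "')")
    parent[[r1]] <- r2
  }
  joints <- lapply(edges, function(e) {
    p1 <- gene_freqs[[e$genes[1]]]; p2 <- gene_freqs[[e$genes[2]]]
    p11 <- solveJointOR(p1, p2, e$or)
    list(genes = e$genes, or = e$or, p11 = p11)
  })
  N <- sum(n_per_phylum)
  withSeed(seed, {
    pres <- matrix(NA, N, length(genes), dimnames = list(NULL, genes))
    # adjacency of the association forest
    adj <- setNames(vector("list", length(genes)), genes)
    for (j in joints) {
      adj[[j$genes[1]]] <- c(adj[[j$genes[1]]], list(j))
      adj[[j$genes[2]]] <- c(adj[[j$genes[2]]], list(j))
    }
    visited <- setNames(rep(FALSE, length(genes)), genes)
    for (g in genes) {
      if (visited[[g]]) next
      # BFS over the component rooted at g
      pres[, g] <- rbinom(N, 1L, gene_freqs[[g]])
      visited[[g]] <- TRUE
      queue <- g
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (j in adj[[cur]]) {
          other <- setdiff(j$genes, cur)
          if (visited[[other]]) next
          pc <- gene_freqs[[cur]]
          p11 <- j$p11  # symmetric in the pair
          p_oth <- gene_freqs[[other]]
          p1g1 <- p11 / pc
          p1g0 <- (p_oth - p11) / (1 - pc)
          stopifnot(p1g1 >= -1e-9, p1g1 <= 1 + 1e-9,
                    p1g0 >= -1e-9, p1g0 <= 1 + 1e-9)
          pr <- ifelse(pres[, cur] == 1L, min(max(p1g1, 0), 1),
                       min(max(p1g0, 0), 1))
          pres[, other] <- rbinom(N, 1L, pr)
          visited[[other]] <- TRUE
          queue <- c(queue, other)
        }
      }
    }
    inv <- data.frame(
      genome_id = sprintf("genome_%04d", seq_len(N)),
      phylum = rep(names(n_per_phylum), n_per_phylum),
      nirK_copies = 1L + rbinom(N, 1L, multi_copy_fraction),
      stringsAsFactors = FALSE)
    for (g in genes) inv[[g]] <- pres[, g] == 1L
    list(inventory = inv,
         truth = list(gene_freqs = gene_freqs, joints = joints,
                      multi_copy_fraction = multi_copy_fraction))
  })
}

#' @rdname generateInventory
#' @export
defaultGeneFreqs <- function() {
  c(nirS = 0.10, nor = 0.71, nosZ = 0.40, napA = 0.55, narG = 0.30,
    nrfA = 0.21, nirB = 0.72, nirV = 0.61)
}

# P(both present) of a 2x2 Bernoulli joint with marginals p1, p2 and
# odds ratio psi
solveJointOR <- function(p1, p2, psi) {
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (psi == 1) {
    p11 <- p1 * p2
  } else {
    a <- psi - 1
    b <- 1 + (p1 + p2) * a
    disc <- b^2 - 4 * a * psi * p1 * p2
    if (disc < 0) stop("no feasible joint for the requested odds ratio")
    p11 <- (b - sqrt(disc)) / (2 * a)
  }
  if (p11 < lo - 1e-9 || p11 > hi + 1e-9)
    stop("odds ratio ", psi, " infeasible for marginals ", p1, ", ", p2)
  min(max(p11, lo), hi)
}

#' Deterministic cohort construction from a per-phylum summary
#'
#' Builds a concrete genome inventory whose classification and summary
#' reproduce a per-phylum specification exactly (no sampling).  Genomes
#' carrying the combined pathway get nrfA (with no nitrate reductase, so
#' they contribute to the nrfA-only DNRA column); denitrification
#' category counts, when given, are realised via the nor/nosZ flags, and
#' default to all-complete.
#'
#' @param spec `data.frame` with columns `phylum`, `n`, `n_combined`, and
#'   optionally `n_complete`, `n_no_nor`, `n_no_nos`, `n_no_nor_no_nos`
#'   (must then sum to `n`).
#' @return Inventory `data.frame` as accepted by [classifyGenomes()].
#' @export
cohortFromSummary <- function(spec) {
  stopifnot(all(c("phylum", "n", "n_combined") %in% names(spec)))
  have_denit <- all(c("n_complete", "n_no_nor", "n_no_nos",
                      "n_no_nor_no_nos") %in% names(spec))
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    if (r$n_combined > r$n || r$n_combined < 0L)
      stop("phylum '", r$phylum, "': n_combined must be in 0..n")
    counts <- if (have_denit) {
      cc <- c(r$n_complete, r$n_no_nor, r$n_no_nos, r$n_no_nor_no_nos)
      if (sum(cc) != r$n)
        stop("phylum '", r$phylum,
             "': denitrification category counts must sum to n")
      cc
    } else c(r$n, 0L, 0L, 0L)
    cat_vec <- rep(DENIT_CATEGORIES, counts)
    rows[[i]] <- data.frame(
      genome_id = sprintf("%s_%03d", r$phylum, seq_len(r$n)),
      phylum = r$phylum, nirK_copies = 1L, nirS = FALSE,
      nor = cat_vec %in% c("complete", "no_nos"),
      nosZ = cat_vec %in% c("complete", "no_nor"),
      napA = FALSE, narG = FALSE,
      nrfA = seq_len(r$n) <= r$n_combined, nirB = FALSE, nirV = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published per-phylum cohort sizes and combined-pathway percentages
#'
#' The per-phylum genome counts and combined denitrification + DNRA
#' percentages printed for a curated survey of 249 NirK-containing
#' genomes across fifteen phyla, bundled as package data.  `n_combined`
#' is reconstructed as the nearest integer of `n * pct / 100`.
#'
#' @return `data.frame`: `phylum`, `n`, `pct_combined`, `n_combined`.
#' @export
cohortCombinedSpec <- function() {
  path <- system.file("extdata", "nirk_cohort_combined.tsv",
                      package = "nirkit", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$n_combined <- as.integer(round(tab$n * tab$pct_combined / 100))
  tab
}
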
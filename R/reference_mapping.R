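## Reference-anchored pairwise alignment.  Every per-sequence feature
## (residue rules, motifs, indels, extensions) is expressed in the residue
## numbering of a 375-aa full-length NirK reference; each candidate is
## anchored to the reference by one global pairwise alignment, and a
## multiple alignment is obtained by stacking the anchored rows.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Default alignment scoring for reference anchoring
#'
#' BLOSUM62 with affine gap penalties: a gap run of length k costs
#' `gap_open + (k - 1) * gap_extend`.  Defaults: open 11, extend 1.
#'
#' @param gap_open,gap_extend Positive gap penalties.
#' @param matrix Substitution matrix with residue dimnames; defaults to
#'   BLOSUM62 (which scores `X` against everything).
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
alignScoring <- function(gap_open = 11, gap_extend = 1, matrix = NULL) {
  if (is.null(matrix)) matrix <- .blosum62()
  stopifnot(gap_open > 0, gap_extend > 0,
            !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment.  The backtrace is made
#' deterministic by a fixed tie-break: substitution is preferred over a gap
#' in `b`, which is preferred over a gap in `a`.
#'
#' @param a,b Protein strings (non-empty, no gaps).
#' @param scoring See [alignScoring()].
#' @return List with `a`, `b` (gapped rows, gap symbol `-`) and `score`.
#' @examples
#' globalAlign("ACDEFG", "ACEFG")
#' @export
globalAlign <- function(a, b, scoring = alignScoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- .alignAffine(a, b, scoring$matrix,
                      paste(rownames(scoring$matrix), collapse = ""),
                      scoring$gap_open, scoring$gap_extend)
  stopifnot(identical(gsub("-", "", res$a, fixed = TRUE), a),
            identical(gsub("-", "", res$b, fixed = TRUE), b))
  res
}

#' The bundled 375-aa surrogate NirK reference
#'
#' The residue numbering used by the whole package is that of a full-length
#' 375-aa NirK reference sequence.  The bundled reference is a synthetic
#' surrogate, generated deterministically, that satisfies all conserved
#' copper-ligand and active-site residue rules (His59, Asp62, His64, His99,
#' Cys100, His110, Met115, His237, His298), carries the Clade I active-site
#' motif TRPHL at positions 234-238, and has locally distinct residues at
#' the boundaries of the clade-diagnostic deletion regions so that deletion
#' gap placement is unambiguous.  A real reference of the same length may
#' be supplied to any function that takes `ref`.
#'
#' @return A single-record protein [NirKSet-class] of length 375.
#' @export
surrogateReference <- function() {
  rules <- defaultResidueRules()
  aa20 <- setdiff(ALPHABETS$protein, "X")
  r <- withSeed(104729L, sample(aa20, 375L, replace = TRUE))
  r[rules$position] <- vapply(strsplit(rules$allowed, "|",
                                       fixed = TRUE), `[`, "", 1L)
  r[234:238] <- strsplit("TRPHL", "")[[1]]
  r[60:64] <- strsplit("VEDAH", "")[[1]]  # Asp62/His64 window
  # make deletion-region boundaries locally distinct so that removing the
  # region yields a unique optimal gap placement
  for (iv in list(c(190L, 196L), c(258L, 264L))) {
    if (r[iv[1] - 1L] == r[iv[2]])
      r[iv[2]] <- setdiff(aa20, r[c(iv[1] - 1L, iv[2] + 1L)])[1L]
    if (r[iv[1]] == r[iv[2] + 1L])
      r[iv[1]] <- setdiff(aa20, r[c(iv[1] - 1L, iv[2] + 1L, iv[2])])[1L]
  }
  # terminal residues must differ from the extension-domain anchors so
  # that terminal extensions map as overhangs, not internal insertions
  if (r[1] == "C") r[1] <- "T"
  if (r[375] == "M") r[375] <- "Q"
  nirkSet(setNames(paste(r, collapse = ""), "NirK_reference_375aa"),
          "protein",
          meta = data.frame(id = "NirK_reference_375aa",
                            species = "surrogate reference",
                            strain = "synthetic", phylum = "synthetic"),
          source = "synthetic")
}

#' Map a protein to reference residue numbering
#'
#' Globally aligns `target` to the reference and classifies every target
#' residue as aligned to a reference position, inserted between reference
#' positions, or part of a terminal overhang; reference positions with no
#' aligned target residue are deleted in the target.
#'
#' @param target Protein string, or a single-sequence protein
#'   [NirKSet-class].
#' @param ref Reference as returned by [surrogateReference()], or a protein
#'   string.
#' @param scoring See [alignScoring()].
#' @param id Id recorded in the map (defaults to the target's id).
#' @return A [ReferenceMap-class].
#' @export
mapToReference <- function(target, ref = surrogateReference(),
                           scoring = alignScoring(), id = NULL) {
  if (is(target, "NirKSet")) {
    stopifnot(length(target) == 1L, target@alphabet == "protein")
    if (is.null(id)) id <- seqIds(target)
    target <- unname(sequences(target))
  }
  if (is(ref, "NirKSet")) ref <- unname(sequences(ref))[1L]
  if (is.null(id)) id <- "target"
  al <- globalAlign(target, ref, scoring)
  ta <- strsplit(al$a, "")[[1]]
  ra <- strsplit(al$b, "")[[1]]
  ti <- cumsum(ta != "-")          # target index per column
  ri <- cumsum(ra != "-")          # reference position per column
  tcol <- ta != "-"
  rcol <- ra != "-"
  target_to_ref <- ifelse(rcol[tcol], ri[tcol], NA_integer_)
  ref_to_target <- ifelse(tcol[rcol], ti[rcol], NA_integer_)
  # overhangs: target residues aligned outside the reference span
  n_over <- sum(tcol & ri == 0L)
  c_over <- sum(tcol & seq_along(ta) > max(which(rcol)))
  obj <- new("ReferenceMap", target_id = id,
             target_to_ref = as.integer(target_to_ref),
             ref_to_target = as.integer(ref_to_target),
             n_term_overhang = as.integer(n_over),
             c_term_overhang = as.integer(c_over),
             score = al$score, aligned_target = al$a, aligned_ref = al$b)
  validObject(obj)
  obj
}

#' Residue of a target at a reference position
#'
#' @param map A [ReferenceMap-class].
#' @param target The target residues (string or single-sequence
#'   [NirKSet-class]) the map was built from.
#' @param position Reference position(s), 1-based.
#' @return Character vector: the amino acid aligned at each position, or
#'   `"deleted"` where the reference position has no target residue.
#' @export
residueAt <- function(map, target, position) {
  if (is(target, "NirKSet")) target <- unname(sequences(target))[1L]
  n <- length(map@ref_to_target)
  if (any(position < 1L | position > n))
    stop("reference position out of range 1..", n)
  idx <- map@ref_to_target[position]
  out <- rep("deleted", length(position))
  ok <- !is.na(idx)
  if (any(ok)) out[ok] <- substring(target, idx[ok], idx[ok])
  out
}

#' Stack reference-anchored rows into a multiple alignment
#'
#' Builds a star multiple alignment from per-sequence reference maps: one
#' column per reference position, plus extra columns for insertions
#' relative to the reference (padded with `-` in the other rows).
#' Terminal overhangs (N-/C-terminal extensions) are excluded, mirroring
#' the practice of trimming an alignment to the region shared by all
#' sequences before phylogenetic analysis.
#'
#' @param maps List of [ReferenceMap-class] built against the same
#'   reference.
#' @param set The protein [NirKSet-class] the maps were built from.
#' @param include_reference Prepend the (ungapped) reference row.
#' @param ref Reference set (only needed when `include_reference = TRUE`).
#' @return Named character vector of equal-length gapped rows.
#' @export
stackAlignment <- function(maps, set, include_reference = FALSE,
                           ref = surrogateReference()) {
  seqs <- sequences(set)
  ids <- vapply(maps, function(m) m@target_id, "")
  stopifnot(all(ids %in% names(seqs)))
  nref <- length(maps[[1]]@ref_to_target)
  # insertions keyed by "after reference position p" (p in 0..nref; terminal
  # overhangs are dropped)
  insAfter <- lapply(maps, function(m) {
    t2r <- m@target_to_ref
    keep <- seq_along(t2r) > m@n_term_overhang &
      seq_along(t2r) <= length(t2r) - m@c_term_overhang
    prev <- cummaxNA(t2r)
    tab <- table(prev[keep & is.na(t2r)])
    setNames(as.integer(tab), names(tab))
  })
  width <- integer(nref + 1L)  # insertion columns after position p (index p+1)
  for (ia in insAfter) {
    p <- as.integer(names(ia))
    width[p + 1L] <- pmax(width[p + 1L], ia)
  }
  rows <- vapply(seq_along(maps), function(k) {
    m <- maps[[k]]
    s <- strsplit(unname(seqs[ids[k]]), "")[[1]]
    t2r <- m@target_to_ref
    keep <- seq_along(t2r) > m@n_term_overhang &
      seq_along(t2r) <= length(t2r) - m@c_term_overhang
    prev <- cummaxNA(t2r)
    out <- character(0)
    for (p in 0:nref) {
      if (p > 0L) {
        i <- m@ref_to_target[p]
        out <- c(out, if (is.na(i)) "-" else s[i])
      }
      if (width[p + 1L] > 0L) {
        ins <- s[keep & is.na(t2r) & !is.na(prev) & prev == p]
        out <- c(out, ins, rep("-", width[p + 1L] - length(ins)))
      }
    }
    paste(out, collapse = "")
  }, "")
  names(rows) <- ids
  if (include_reference) {
    rmap <- mapToReference(ref, ref)
    rrow <- stackAlignmentRefRow(rmap, ref, width, nref)
    rows <- c(setNames(rrow, seqIds(ref)), rows)
  }
  rows
}

# reference row padded with the same insertion columns
stackAlignmentRefRow <- function(rmap, ref, width, nref) {
  s <- strsplit(unname(sequences(ref))[1L], "")[[1]]
  out <- character(0)
  for (p in 0:nref) {
    if (p > 0L) out <- c(out, s[p])
    if (width[p + 1L] > 0L) out <- c(out, rep("-", width[p + 1L]))
  }
  paste(out, collapse = "")
}

# running maximum ignoring NA, NA before first value -> 0
cummaxNA <- function(x) {
  out <- integer(length(x))
  cur <- 0L
  for (i in seq_along(x)) {
    if (!is.na(x[i])) cur <- max(cur, x[i])
    out[i] <- cur
  }
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
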
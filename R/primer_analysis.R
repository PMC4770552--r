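## In-silico evaluation of degenerate nirK primers: best binding sites,
## per-position mismatch profiles by clade, binding-region sequence
## logos, and amplicon prediction.

# reverse complement that preserves IUPAC degeneracy
revcompIupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "")[[1]])
    paste(comp[ch], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Best binding site of a degenerate primer on a sequence
#'
#' Scans every offset of the primer along the appropriate strand (reverse
#' primers are scanned against the reverse complement of the template).  A
#' position mismatches iff the IUPAC base sets of primer and template
#' symbol do not intersect.  The site with the fewest total mismatches is
#' returned; ties go to the leftmost site on the scanned strand.
#'
#' @param primer A [Primer-class].
#' @param seq Nucleotide string or single-sequence nucleotide
#'   [NirKSet-class]; must be at least as long as the primer.
#' @param three_prime_window Width k of the 3' window in which mismatches
#'   are counted separately (default 3).
#' @return List: `sequence_id`, `site_start` (1-based on the scanned
#'   strand), `strand` (`"given"` or `"reverse_complement"`),
#'   `per_position_mismatches` (logical, primer 5'->3'),
#'   `total_mismatches`, `three_prime_mismatches`.
#' @export
bestBindingSite <- function(primer, seq, three_prime_window = 3L) {
  id <- "seq"
  if (is(seq, "NirKSet")) {
    stopifnot(length(seq) == 1L, seq@alphabet == "nucleotide")
    id <- seqIds(seq)
    seq <- unname(sequences(seq))
  }
  seq <- toupper(seq)
  p <- strsplit(primer@sequence, "")[[1]]
  L <- length(p)
  if (nchar(seq) < L)
    stop("sequence shorter than primer (", nchar(seq), " < ", L, ")")
  strand <- "given"
  if (primer@orientation == "reverse") {
    seq <- revcompIupac(seq)
    strand <- "reverse_complement"
  }
  s <- strsplit(seq, "")[[1]]
  compat <- .iupacCompatMatrix()
  n_off <- length(s) - L + 1L
  # mismatch count per offset via columnwise lookup
  mm_total <- integer(n_off)
  for (k in seq_len(L))
    mm_total <- mm_total + !compat[p[k], s[k:(k + n_off - 1L)]]
  best <- which.min(mm_total)  # leftmost minimum
  site <- s[best:(best + L - 1L)]
  mm <- !compat[cbind(p, site)]
  k <- min(three_prime_window, L)
  list(sequence_id = id, site_start = as.integer(best), strand = strand,
       per_position_mismatches = unname(mm),
       total_mismatches = sum(mm),
       three_prime_mismatches = sum(mm[(L - k + 1L):L]))
}

#' Per-clade, per-position primer mismatch profile
#'
#' For each clade group and primer position, the fraction of sequences
#' mismatching at that position of their best binding site.  The combined
#' profile over all groups equals the size-weighted mean of the per-group
#' profiles.
#'
#' @param primer A [Primer-class].
#' @param set Nucleotide [NirKSet-class].
#' @param group_of Named character vector mapping sequence ids to clade
#'   labels.
#' @param three_prime_window Passed to [bestBindingSite()].
#' @return `data.frame` with columns `group`, `n`, and `pos1..posL`
#'   mismatch fractions; includes a `combined` row over all sequences.
#'   Empty groups are omitted (with a warning).
#' @export
mismatchProfile <- function(primer, set, group_of,
                            three_prime_window = 3L) {
  stopifnot(is(set, "NirKSet"), set@alphabet == "nucleotide")
  seqs <- sequences(set)
  hits <- lapply(names(seqs), function(id)
    bestBindingSite(primer, unname(seqs[id]), three_prime_window))
  mm <- do.call(rbind, lapply(hits, `[[`, "per_position_mismatches"))
  rownames(mm) <- names(seqs)
  glab <- group_of[names(seqs)]
  if (anyNA(glab)) stop("group_of must cover every sequence id")
  groups <- sort(unique(glab))
  empty <- setdiff(unique(group_of), glab)
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  rows <- lapply(groups, function(g) {
    sub <- mm[glab == g, , drop = FALSE]
    c(n = nrow(sub), colMeans(sub))
  })
  out <- data.frame(group = c(groups, "combined"),
                    do.call(rbind, c(rows, list(c(n = nrow(mm),
                                                  colMeans(mm))))),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("group", "n", paste0("pos", seq_len(ncol(mm))))
  out
}

#' Sequence logo of the primer binding region
#'
#' Computes per-column symbol frequencies and information content for the
#' aligned binding regions of a set of sequences.  Information content is
#' `log2(4) - H` bits where `H` is the Shannon entropy of the column's
#' base distribution (no small-sample correction).
#'
#' @param set Nucleotide [NirKSet-class].
#' @param primer A [Primer-class] (defines the region width and strand).
#' @param anchors Named integer vector: binding-site start per sequence id
#'   on the scanned strand.  When `NULL`, each sequence's best binding
#'   site is used.
#' @return List with `freq` (4 x L matrix of A/C/G/T frequencies; columns
#'   sum to 1) and `ic` (numeric vector of per-column bits in \[0, 2\]).
#' @export
bindingRegionLogo <- function(set, primer, anchors = NULL) {
  stopifnot(is(set, "NirKSet"), set@alphabet == "nucleotide")
  seqs <- sequences(set)
  L <- nchar(primer@sequence)
  regions <- vapply(names(seqs), function(id) {
    s <- toupper(unname(seqs[id]))
    if (primer@orientation == "reverse") s <- revcompIupac(s)
    start <- if (is.null(anchors)) {
      bestBindingSite(primer, unname(seqs[id]))$site_start
    } else anchors[[id]]
    substr(s, start, start + L - 1L)
  }, "")
  mat <- do.call(rbind, strsplit(regions, ""))
  bases <- c("A", "C", "G", "T")
  freq <- apply(mat, 2, function(col) {
    col <- col[col %in% bases]  # ambiguous symbols carry no count
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / max(sum(tab), 1L)
  })
  rownames(freq) <- bases
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    log2(4) - sum(-f * log2(f))
  })
  list(freq = freq, ic = as.numeric(ic))
}

#' In-silico PCR amplicon prediction
#'
#' Finds every pairing of a forward-primer site and a downstream
#' reverse-primer site whose per-site mismatch totals are within the
#' budget, optionally requiring a clean 3' window on both sites.
#'
#' @param fwd,rev Forward and reverse [Primer-class] objects (oriented as
#'   declared; the reverse primer binds the reverse strand).
#' @param seq Nucleotide string or single-sequence [NirKSet-class].
#' @param max_mismatch Maximum mismatches allowed per site.
#' @param require_3prime_clean Exclude sites with any mismatch in the 3'
#'   window.
#' @param three_prime_window 3' window width k.
#' @return `data.frame` of amplicons: `start`, `end` (1-based on the given
#'   strand, inclusive), `length`, `fwd_mismatches`, `rev_mismatches`.
#' @export
inSilicoPCR <- function(fwd, rev, seq, max_mismatch = 0L,
                        require_3prime_clean = FALSE,
                        three_prime_window = 3L) {
  if (is(seq, "NirKSet")) seq <- unname(sequences(seq))[1L]
  seq <- toupper(seq)
  stopifnot(fwd@orientation == "forward", rev@orientation == "reverse")
  n <- nchar(seq)
  compat <- .iupacCompatMatrix()
  s <- strsplit(seq, "")[[1]]

  siteScan <- function(p_chars) {
    L <- length(p_chars)
    n_off <- n - L + 1L
    if (n_off < 1L) return(NULL)
    mm <- matrix(FALSE, n_off, L)
    for (k in seq_len(L))
      mm[, k] <- !compat[p_chars[k], s[k:(k + n_off - 1L)]]
    mm
  }

  pf <- strsplit(fwd@sequence, "")[[1]]
  # reverse primer site on the given strand is the reverse complement of
  # the primer; its 3' end is the leftmost base of that site
  pr <- strsplit(revcompIupac(rev@sequence), "")[[1]]
  mmF <- siteScan(pf)
  mmR <- siteScan(pr)
  if (is.null(mmF) || is.null(mmR))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer()))
  kF <- min(three_prime_window, length(pf))
  kR <- min(three_prime_window, length(pr))
  okF <- rowSums(mmF) <= max_mismatch
  okR <- rowSums(mmR) <= max_mismatch
  if (require_3prime_clean) {
    okF <- okF & rowSums(mmF[, (length(pf) - kF + 1L):length(pf),
                             drop = FALSE]) == 0L
    okR <- okR & rowSums(mmR[, seq_len(kR), drop = FALSE]) == 0L
  }
  fs <- which(okF)
  rs <- which(okR)
  out <- list()
  for (f in fs) for (r in rs) {
    if (r >= f + length(pf)) {  # reverse site strictly downstream
      out[[length(out) + 1L]] <- data.frame(
        start = f, end = r + length(pr) - 1L,
        length = r + length(pr) - f,
        fwd_mismatches = sum(mmF[f, ]), rev_mismatches = sum(mmR[r, ]))
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer()))
  do.call(rbind, out)
}
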
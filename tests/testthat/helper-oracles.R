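# Independent oracles used across the test files.  These deliberately
# avoid the package's own code paths: base sets are hand-coded, the
# alignment oracle enumerates every monotone alignment, the binding-site
# oracle scans every offset with per-position set intersection.

# hand-coded IUPAC nucleotide base sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T"))

oracleIupacCompatible <- function(a, b)
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L

# Best global alignment score by exhaustive enumeration of all monotone
# alignments (move sequences), scoring gap runs as open + (k-1) * extend.
# No memoisation: every complete alignment is visited.
oracleAlignScore <- function(a, b, scoring = nirkit::alignScoring()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  S <- scoring$matrix; go <- scoring$gap_open; ge <- scoring$gap_extend
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1L, j + 1L, score + S[av[i], bv[j]], "M")
    if (i <= length(av))
      rec(i + 1L, j, score - if (last == "X") ge else go, "X")
    if (j <= length(bv))
      rec(i, j + 1L, score - if (last == "Y") ge else go, "Y")
  }
  rec(1L, 1L, 0, "M")
  best
}

# Minimal-mismatch binding site by scanning every offset, leftmost tie
oracleBestSite <- function(primer_seq, template) {
  p <- strsplit(primer_seq, "")[[1]]
  s <- strsplit(template, "")[[1]]
  L <- length(p)
  mm <- vapply(seq_len(length(s) - L + 1L), function(off)
    sum(!mapply(oracleIupacCompatible, p, s[off:(off + L - 1L)])), 0)
  list(start = which.min(mm), mismatches = min(mm))
}

# Hypergeometric joint-presence pmf by enumerating all placements of the
# second gene's presences over the N genomes
oracleHyperPmf <- function(N, N1, N2) {
  placements <- combn(N, N2)
  x <- seq_len(N) <= N1
  js <- apply(placements, 2, function(idx) sum(x[idx]))
  tab <- table(js) / ncol(placements)
  setNames(as.numeric(tab), names(tab))
}

# Mean pairwise identity recount (pairwise deletion), independent loop
oraclePairwiseIdentity <- function(rows) {
  n <- length(rows)
  mats <- strsplit(rows, "")
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- mats[[i]]; b <- mats[[j]]
    ok <- a != "-" & b != "-"
    vals <- c(vals, 100 * sum(a[ok] == b[ok]) / sum(ok))
  }
  mean(vals)
}

# random protein string
randProtein <- function(n)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")

# random nucleotide string
randDNA <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# one-decimal rounding, half away from zero (cohort table convention)
halfUp1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
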
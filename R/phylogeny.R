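## Distance-based phylogenetics: amino-acid difference counts with
## complete or pairwise deletion, neighbour joining with a deterministic
## tie-break, and column-bootstrap supports.  Trees are returned as
## ape "phylo" objects and serialised through ape.

#' Pairwise distance matrix from a gapped alignment
#'
#' `count_differences` counts the differing retained columns (the
#' "number of differences" amino-acid model); `p_distance` divides that
#' count by the number of retained columns.  Under complete deletion
#' every column containing at least one gap in any row is removed before
#' counting, so all pairs are computed over the same column set; under
#' pairwise deletion only columns gapped in one of the two rows compared
#' are dropped for that pair.
#'
#' @param aln Named character vector of equal-length gapped rows (gap
#'   symbol `-`), or a matrix of single characters with rownames.
#' @param method `"count_differences"` or `"p_distance"`.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return Symmetric numeric matrix with zero diagonal and id dimnames.
#' @export
distanceMatrix <- function(aln,
                           method = c("count_differences", "p_distance"),
                           deletion = c("complete", "pairwise")) {
  method <- match.arg(method)
  deletion <- match.arg(deletion)
  mat <- if (is.matrix(aln)) aln else {
    stopifnot(length(unique(nchar(aln))) == 1L)
    do.call(rbind, strsplit(aln, ""))
  }
  if (is.null(rownames(mat)) && !is.matrix(aln)) rownames(mat) <- names(aln)
  n <- nrow(mat)
  stopifnot(n >= 2L)
  if (deletion == "complete") {
    keep <- colSums(mat == "-") == 0L
    if (!any(keep))
      stop("complete deletion removed every column; ",
           "no gap-free columns shared by all sequences")
    mat <- mat[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- if (deletion == "pairwise") a != "-" & b != "-"
          else rep(TRUE, length(a))
    nd <- sum(a[ok] != b[ok])
    d[i, j] <- d[j, i] <-
      if (method == "count_differences") nd else nd / sum(ok)
  }
  d
}

#' Neighbour-joining tree
#'
#' Standard neighbour joining (Q-matrix agglomeration).  On an additive
#' distance matrix the generating tree is recovered exactly, topology and
#' branch lengths.  Ties in the Q matrix are broken deterministically by
#' the lowest index pair (row-major).  A negative branch length arising
#' from non-additive input is clamped to zero with the deficit
#' transferred to its sibling branch, preserving the path length between
#' the joined pair.
#'
#' @param dm Symmetric distance matrix with id dimnames, n >= 3.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbour joining requires at least 3 taxa")
  stopifnot(isSymmetric(unname(dm)), all(diag(dm) == 0))
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  frag <- ids  # newick fragment per active node
  d <- dm
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest index pair among minima, scanning i < j row-major
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(d2) <- colnames(d2) <- seq_len(m - 1L)
    d <- d2
  }
  # closed-form star resolution of the final three nodes
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  cc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ln <- pmax(c(a, b, cc), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], ln[1], frag[2], ln[2], frag[3], ln[3])
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement; the distance matrix (and
#' its deletion policy) is recomputed per replicate, so complete deletion
#' operates on the resampled columns.  The support of an internal edge is
#' the percentage of replicate trees containing its bipartition, attached
#' as node labels of the returned tree.
#'
#' @inheritParams distanceMatrix
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @return The NJ tree of the full alignment, with `node.label` set to
#'   bootstrap percentages (root label empty).
#' @export
bootstrapSupport <- function(aln,
                             method = c("count_differences", "p_distance"),
                             deletion = c("complete", "pairwise"),
                             replicates = 100L, seed = 1L) {
  method <- match.arg(method)
  deletion <- match.arg(deletion)
  stopifnot(replicates >= 1L)
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  tree <- neighborJoining(distanceMatrix(mat, method, deletion))
  boot <- withSeed(seed, lapply(seq_len(replicates), function(b) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    neighborJoining(distanceMatrix(mat[, cols, drop = FALSE],
                                   method, deletion))
  }))
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  support <- round(100 * counts / replicates)
  support[is.na(support)] <- NA
  tree$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(tree, "replicates") <- replicates
  tree
}

#' Support of one bipartition across replicate trees
#'
#' @param trees List of [ape::phylo] trees over the same tips.
#' @param tips Character vector: one side of the bipartition.
#' @return Percentage of trees whose unrooted splits contain the
#'   bipartition.
#' @export
bipartitionSupport <- function(trees, tips) {
  all_tips <- trees[[1]]$tip.label
  target <- sort(tips)
  comp <- sort(setdiff(all_tips, tips))
  hit <- vapply(trees, function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    any(vapply(pp, function(p) {
      s <- sort(labs[p])
      identical(s, target) || identical(s, comp)
    }, TRUE))
  }, TRUE)
  100 * mean(hit)
}

#' Serialise / parse trees as newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; bootstrap
#' supports stored in `node.label` are emitted as internal node labels.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional file path; when `NULL` the newick string is
#'   returned.
#' @return `toNewick()`: newick string (invisibly, the path when writing
#'   to file); `fromNewick()`: a `phylo`.
#' @export
toNewick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

#' @rdname toNewick
#' @param text Newick string (when `path` is `NULL`).
#' @export
fromNewick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}
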
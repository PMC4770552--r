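## Denitrification / DNRA pathway classification of genome gene
## inventories, per-phylum cohort summaries, and probabilistic
## co-occurrence statistics between genes.

INVENTORY_GENES <- c("nirS", "nor", "nosZ", "napA", "narG", "nrfA",
                     "nirB", "nirV")

DENIT_CATEGORIES <- c("complete", "no_nor", "no_nos", "no_nor_no_nos")
DNRA_LABELS <- c("nap_nrfA", "nar_nrfA", "nrfA_only",
                 "nap_nirB", "nar_nirB", "nirB_only")

# round half away from zero to `digits` decimals (table convention)
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify one genome inventory into pathway categories
#'
#' The denitrification category follows from the nitric oxide and nitrous
#' oxide reductase flags (a nitrite reductase is guaranteed by cohort
#' admission): both present = `complete`; only nosZ = `no_nor`; only nor =
#' `no_nos`; neither = `no_nor_no_nos`.  DNRA labels are non-exclusive:
#' each DNRA nitrite reductase present (nrfA, nirB) is paired with napA
#' and/or narG when those nitrate reductases are present, or labelled
#' `_only` when neither is; a genome with both nrfA and nirB contributes
#' to both branches.  `combined` records the joint genomic potential for
#' denitrification and DNRA (nrfA or nirB alongside the nitrite
#' reductase).
#'
#' @param nirK_copies Integer nirK copy number (>= 0).
#' @param nirS,nor,nosZ,napA,narG,nrfA,nirB Logical presence flags.
#' @return List: `denit_category`, `dnra_labels` (character vector,
#'   possibly empty), `combined`.
#' @export
classifyGenome <- function(nirK_copies, nirS = FALSE, nor = FALSE,
                           nosZ = FALSE, napA = FALSE, narG = FALSE,
                           nrfA = FALSE, nirB = FALSE) {
  if (nirK_copies < 1L && !isTRUE(nirS))
    stop("genome lacks a nitrite reductase (nirK or nirS); ",
         "not a denitrifier sensu stricto")
  denit <- if (nor && nosZ) "complete"
  else if (nosZ) "no_nor"
  else if (nor) "no_nos"
  else "no_nor_no_nos"
  labels <- character()
  for (red in c("nrfA", "nirB")) {
    if (!get(red)) next
    tag <- if (red == "nrfA") "nrfA" else "nirB"
    any_nitrate <- FALSE
    if (napA) { labels <- c(labels, paste0("nap_", tag)); any_nitrate <- TRUE }
    if (narG) { labels <- c(labels, paste0("nar_", tag)); any_nitrate <- TRUE }
    if (!any_nitrate) labels <- c(labels, paste0(tag, "_only"))
  }
  list(denit_category = denit, dnra_labels = labels,
       combined = nrfA || nirB)
}

#' Classify every genome of an inventory table
#'
#' @param inventory `data.frame` with columns `genome_id`, `phylum`,
#'   `nirK_copies` and logical columns nirS, nor, nosZ, napA, narG,
#'   nrfA, nirB (nirV optional).
#' @return The input with added columns `denit_category`, `combined`, and
#'   one logical column per DNRA label.
#' @export
classifyGenomes <- function(inventory) {
  need <- c("genome_id", "phylum", "nirK_copies", "nirS", "nor", "nosZ",
            "napA", "narG", "nrfA", "nirB")
  stopifnot(all(need %in% names(inventory)))
  calls <- lapply(seq_len(nrow(inventory)), function(i) {
    r <- inventory[i, ]
    classifyGenome(r$nirK_copies, r$nirS, r$nor, r$nosZ, r$napA, r$narG,
                   r$nrfA, r$nirB)
  })
  inventory$denit_category <- vapply(calls, `[[`, "", "denit_category")
  inventory$combined <- vapply(calls, `[[`, TRUE, "combined")
  for (lab in DNRA_LABELS)
    inventory[[lab]] <- vapply(calls, function(x) lab %in% x$dnra_labels,
                               TRUE)
  inventory
}

#' Per-phylum and total cohort summary
#'
#' Percentages per phylum plus a Total row computed from the raw calls
#' (never from rounded per-phylum values), each rounded to one decimal,
#' half away from zero.
#'
#' @param calls Output of [classifyGenomes()].
#' @return `data.frame`: one row per phylum plus `Total`; columns `n`,
#'   `pct_multi_copy`, one `pct_` column per denitrification category and
#'   DNRA label, `pct_combined`, and `pct_nirV` when present.
#' @export
summarizeCohort <- function(calls) {
  stopifnot(nrow(calls) >= 1L, "denit_category" %in% names(calls))
  one <- function(sub, label) {
    pct <- function(x) roundHalfUp(100 * mean(x), 1L)
    row <- data.frame(phylum = label, n = nrow(sub),
                      pct_multi_copy = pct(sub$nirK_copies >= 2L))
    for (cat in DENIT_CATEGORIES)
      row[[paste0("pct_", cat)]] <- pct(sub$denit_category == cat)
    for (lab in DNRA_LABELS)
      row[[paste0("pct_", lab)]] <- pct(sub[[lab]])
    row$pct_combined <- pct(sub$combined)
    if ("nirV" %in% names(sub)) row$pct_nirV <- pct(sub$nirV)
    row
  }
  phyla <- sort(unique(calls$phylum))
  out <- do.call(rbind, c(
    lapply(phyla, function(p) one(calls[calls$phylum == p, ], p)),
    list(one(calls, "Total"))))
  rownames(out) <- NULL
  out
}

#' Hypergeometric co-occurrence test for two binary vectors
#'
#' Conditional on the marginals N1 = sum(x), N2 = sum(y), the number of
#' joint presences j follows the hypergeometric distribution
#' P(j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2).  `p_lt` and `p_gt` are
#' the inclusive lower and upper tail probabilities of the observed j
#' (they overlap at P(j_obs), so they sum to >= 1).  `phi` is the Pearson
#' correlation of the two binary vectors, with a two-sided p-value from
#' the t distribution on N - 2 df (`phi_p`); phi is undefined (NA,
#' flagged) for constant vectors while the tails are still computed.
#'
#' @param x,y Binary (0/1 or logical) vectors of equal length N >= 2.
#' @return List: `N`, `N1`, `N2`, `j_obs`, `expected`, `p_lt`, `p_gt`,
#'   `phi`, `phi_p`, `phi_defined`.
#' @export
cooccurrenceTest <- function(x, y) {
  x <- as.integer(as.logical(x)); y <- as.integer(as.logical(y))
  N <- length(x)
  stopifnot(N >= 2L, length(y) == N, !anyNA(x), !anyNA(y))
  N1 <- sum(x); N2 <- sum(y); j_obs <- sum(x & y)
  js <- max(0L, N1 + N2 - N):min(N1, N2)
  # P(j) via log binomial coefficients (numerically exact to ~1e-12)
  logp <- lchoose(N1, js) + lchoose(N - N1, N2 - js) - lchoose(N, N2)
  pj <- exp(logp)
  p_lt <- sum(pj[js <= j_obs])
  p_gt <- sum(pj[js >= j_obs])
  phi_defined <- N1 > 0L && N1 < N && N2 > 0L && N2 < N
  if (phi_defined) {
    phi <- cor(x, y)
    phi_p <- if (N > 2L) {
      tt <- phi * sqrt((N - 2) / max(1 - phi^2, .Machine$double.eps))
      2 * pt(-abs(tt), df = N - 2)
    } else NA_real_  # no residual df
  } else {
    phi <- NA_real_; phi_p <- NA_real_
  }
  list(N = N, N1 = N1, N2 = N2, j_obs = j_obs,
       expected = N1 * N2 / N, p_lt = min(p_lt, 1), p_gt = min(p_gt, 1),
       phi = phi, phi_p = phi_p, phi_defined = phi_defined)
}

#' All-pairs gene co-occurrence screen
#'
#' Runs [cooccurrenceTest()] on every unordered pair of gene columns and
#' applies Benjamini-Hochberg correction across pairs to the two-sided
#' co-occurrence p-value (`2 * min(p_lt, p_gt)`, capped at 1).
#'
#' @param inventory `data.frame` with logical gene columns.
#' @param genes Character vector of gene column names (>= 2).
#' @return `data.frame`, one row per pair: `gene1`, `gene2`, `N`, `N1`,
#'   `N2`, `j_obs`, `expected`, `p_lt`, `p_gt`, `phi`, `phi_p`,
#'   `p_two_sided`, `p_adj`.
#' @export
pairwiseGeneScreen <- function(inventory, genes = INVENTORY_GENES[1:7]) {
  stopifnot(length(genes) >= 2L, all(genes %in% names(inventory)))
  prs <- combn(genes, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    g1 <- prs[1, k]; g2 <- prs[2, k]
    ct <- cooccurrenceTest(inventory[[g1]], inventory[[g2]])
    data.frame(gene1 = g1, gene2 = g2, N = ct$N, N1 = ct$N1, N2 = ct$N2,
               j_obs = ct$j_obs, expected = ct$expected, p_lt = ct$p_lt,
               p_gt = ct$p_gt, phi = ct$phi, phi_p = ct$phi_p,
               p_two_sided = min(1, 2 * min(ct$p_lt, ct$p_gt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_two_sided, method = "BH")
  out
}

#' Read / write genome inventory tables (TSV)
#'
#' One row per genome: `genome_id`, `phylum`, integer `nirK_copies`, and
#' 0/1 columns for the other genes.
#'
#' @param path File path.
#' @return `readInventory()`: a `data.frame` with logical gene columns.
#' @export
readInventory <- function(path) {
  inv <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "phylum", "nirK_copies")
  stopifnot(all(need %in% names(inv)))
  for (g in intersect(INVENTORY_GENES, names(inv)))
    inv[[g]] <- as.logical(inv[[g]])
  inv
}

#' @rdname readInventory
#' @param inventory Inventory `data.frame` to write.
#' @export
writeInventory <- function(inventory, path) {
  out <- inventory
  for (g in intersect(INVENTORY_GENES, names(out)))
    out[[g]] <- as.integer(out[[g]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
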
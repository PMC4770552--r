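test_that("genome classification follows the pathway category rules", {
  c1 <- classifyGenome(1, nor = TRUE, nosZ = TRUE)
  expect_equal(c1$denit_category, "complete")
  expect_false(c1$combined)
  expect_length(c1$dnra_labels, 0L)

  expect_equal(classifyGenome(1)$denit_category, "no_nor_no_nos")
  expect_equal(classifyGenome(1, nosZ = TRUE)$denit_category, "no_nor")
  expect_equal(classifyGenome(1, nor = TRUE)$denit_category, "no_nos")

  # DNRA labels are non-exclusive across reductase and nitrate branches
  c2 <- classifyGenome(1, napA = TRUE, nrfA = TRUE, nirB = TRUE)
  expect_setequal(c2$dnra_labels, c("nap_nrfA", "nap_nirB"))
  expect_true(c2$combined)
  c3 <- classifyGenome(1, napA = TRUE, narG = TRUE, nrfA = TRUE)
  expect_setequal(c3$dnra_labels, c("nap_nrfA", "nar_nrfA"))
  expect_equal(classifyGenome(1, nrfA = TRUE)$dnra_labels, "nrfA_only")
  expect_equal(classifyGenome(1, nirB = TRUE)$dnra_labels, "nirB_only")

  # a genome with no nitrite reductase is not a denitrifier sensu stricto
  expect_error(classifyGenome(0), "nitrite reductase")
  expect_equal(classifyGenome(0, nirS = TRUE)$denit_category,
               "no_nor_no_nos")
})

test_that("classification is total over all flag combinations with nirK present", {
  flags <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(flags) <- c("nirS", "nor", "nosZ", "napA", "narG", "nrfA", "nirB")
  for (i in seq_len(nrow(flags))) {
    cl <- do.call(classifyGenome, c(list(nirK_copies = 1), flags[i, ]))
    expect_true(cl$denit_category %in%
                  c("complete", "no_nor", "no_nos", "no_nor_no_nos"))
    expect_equal(cl$combined, flags$nrfA[i] || flags$nirB[i])
  }
})

test_that("cohort summaries recount correctly and category percentages sum to 100", {
  one <- data.frame(genome_id = "g", phylum = "Firmicutes",
                    nirK_copies = 1L, nirS = FALSE, nor = TRUE,
                    nosZ = TRUE, napA = FALSE, narG = FALSE, nrfA = FALSE,
                    nirB = FALSE, nirV = FALSE)
  s1 <- summarizeCohort(classifyGenomes(one))
  expect_equal(s1$pct_complete, c(100, 100))
  expect_equal(s1$phylum, c("Firmicutes", "Total"))

  gen <- generateInventory(c(pA = 40L, pB = 60L), seed = 14)
  calls <- classifyGenomes(gen$inventory)
  s <- summarizeCohort(calls)
  # brute-force recount of the Total row from the raw calls
  cat_cols <- paste0("pct_", c("complete", "no_nor", "no_nos",
                               "no_nor_no_nos"))
  expect_equal(rowSums(s[cat_cols]), rep(100, nrow(s)), tolerance = 0.003,
               ignore_attr = TRUE)
  tot <- s[s$phylum == "Total", ]
  expect_equal(tot$n, 100L)
  expect_equal(tot$pct_combined,
               round(100 * mean(calls$nrfA | calls$nirB), 1))
  pA <- s[s$phylum == "pA", ]
  sub <- calls[calls$phylum == "pA", ]
  expect_equal(pA$pct_complete,
               round(100 * mean(sub$denit_category == "complete"), 1))
})

test_that("hypergeometric tails match exhaustive enumeration of placements", {
  # forced co-occurrence: N=2, N1=2, N2=1 -> both tails 1
  ct <- cooccurrenceTest(c(1, 1), c(1, 0))
  expect_equal(ct$p_lt, 1)
  expect_equal(ct$p_gt, 1)

  # N=4, N1=2, N2=2, j=2 -> p_gt = 1/6 (1 of the C(4,2) placements)
  ct2 <- cooccurrenceTest(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(ct2$p_gt, 1 / 6)
  expect_equal(ct2$expected, 1)

  # perfect avoidance: phi = -1
  ct3 <- cooccurrenceTest(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(ct3$phi, -1)
  expect_equal(ct3$p_lt, 1 / 6)

  # pmf against full enumeration for a batch of small configurations
  for (cfg in list(c(5, 2, 3), c(7, 4, 4), c(9, 3, 6), c(10, 5, 5))) {
    N <- cfg[1]; N1 <- cfg[2]; N2 <- cfg[3]
    pmf <- oracleHyperPmf(N, N1, N2)
    for (j in as.integer(names(pmf))) {
      x <- as.integer(seq_len(N) <= N1)
      y <- integer(N); y[seq_len(j)] <- 1L
      if (N2 > j) y[(N1 + 1):(N1 + N2 - j)] <- 1L
      ct <- cooccurrenceTest(x, y)
      expect_equal(ct$j_obs, j)
      want_lt <- sum(pmf[as.integer(names(pmf)) <= j])
      expect_equal(ct$p_lt, want_lt, tolerance = 1e-12)
    }
  }

  # tails overlap at P(j_obs): p_lt + p_gt >= 1
  set.seed(6)
  for (rep in 1:20) {
    x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.4)
    ct <- cooccurrenceTest(x, y)
    expect_gte(ct$p_lt + ct$p_gt, 1)
    expect_true(ct$phi >= -1 && ct$phi <= 1)
  }

  # constant vector: phi flagged undefined, tails still computed
  ct4 <- cooccurrenceTest(c(1, 1, 1), c(1, 0, 1))
  expect_false(ct4$phi_defined)
  expect_true(is.na(ct4$phi))
  expect_equal(ct4$p_lt, 1)
})

test_that("the pairwise screen emits one statistic per unordered pair with BH correction", {
  gen <- generateInventory(c(p = 80L), seed = 23)
  for (k in c(2, 4, 7)) {
    genes <- names(defaultGeneFreqs())[seq_len(k)]
    sc <- pairwiseGeneScreen(gen$inventory, genes)
    expect_equal(nrow(sc), k * (k - 1) / 2)
  }
  sc <- pairwiseGeneScreen(gen$inventory)
  expect_equal(sc$p_adj, p.adjust(sc$p_two_sided, "BH"))
  expect_true(all(sc$p_adj >= sc$p_two_sided - 1e-12))
})

test_that("a planted negative association is detected with the right sign", {
  hits <- 0L
  for (s in 1:40) {
    gen <- generateInventory(c(p = 250L),
                             associations = list(
                               list(genes = c("narG", "nrfA"), or = 0.2)),
                             seed = 1000L + s)
    ct <- cooccurrenceTest(gen$inventory$narG, gen$inventory$nrfA)
    if (ct$p_lt < 0.05 && ct$phi < 0) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("inventory TSV round trip preserves flags and copy numbers", {
  gen <- generateInventory(c(pA = 10L), seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeInventory(gen$inventory, f)
  back <- readInventory(f)
  expect_equal(back, gen$inventory)
})
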
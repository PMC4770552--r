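test_that("generators are pure functions of config and seed", {
  cfg <- seqGenConfig(n_clade1 = 5, n_clade2 = 5, substitution_rate = 0.1,
                      seed = 77)
  g1 <- generateNirkSet(cfg)
  g2 <- generateNirkSet(cfg)
  expect_identical(sequences(g1$set), sequences(g2$set))
  expect_identical(g1$truth, g2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeFasta(g1$set, f1); writeFasta(g2$set, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 1),
                   readBin(f2, "raw", file.size(f2) + 1))

  g3 <- generateNirkSet(seqGenConfig(n_clade1 = 5, n_clade2 = 5,
                                     substitution_rate = 0.1, seed = 78))
  expect_false(identical(sequences(g1$set), sequences(g3$set)))

  i1 <- generateInventory(c(p = 30L), seed = 5)
  i2 <- generateInventory(c(p = 30L), seed = 5)
  expect_identical(i1$inventory, i2$inventory)
})

test_that("config validation rejects out-of-range rates and overlapping regions", {
  expect_error(seqGenConfig(substitution_rate = 1), "\\[0, 1\\)")
  expect_error(seqGenConfig(substitution_rate = -0.1), "\\[0, 1\\)")
  bad <- defaultIndelRegions()
  bad$start[1] <- 230L; bad$end[1] <- 240L  # overlaps the His237 window
  expect_error(seqGenConfig(indel_regions = bad), "protected")
})

test_that("zero-noise generator output is recovered perfectly by every caller", {
  gen <- generateNirkSet(seqGenConfig(n_clade1 = 5, n_clade2 = 5,
                                      seed = 31))
  cls <- classifySequences(gen$set)
  p <- cls$profiles[match(gen$truth$id, cls$profiles$id), ]
  expect_equal(sum(p$is_nirk), 10L)
  expect_equal(p$clade, gen$truth$clade)
  expect_equal(p$his237_motif, gen$truth$his237_motif)
  expect_equal(p$asp62_motif, gen$truth$asp62_motif)
  expect_equal(p$linker_deleted, gen$truth$linker_deleted)
  expect_equal(p$tower_deleted, gen$truth$tower_deleted)
  expect_equal(p$heme_c, gen$truth$extension == "heme")
  expect_equal(p$cupredoxin, gen$truth$extension == "cupredoxin")
})

test_that("extension construction arithmetic gives full-length overhangs", {
  gen <- generateNirkSet(seqGenConfig(n_clade1 = 0, n_clade2 = 10,
                                      fraction_with_heme_ext = 1,
                                      fraction_with_cupredoxin_ext = 0,
                                      seed = 13))
  cls <- classifySequences(gen$set)
  # C + x2 + C + H + x50 + M is 56 residues before any padding
  expect_true(all(cls$profiles$c_overhang >= 56))
  expect_true(all(cls$profiles$heme_c))
})

test_that("back-translation is a uniform synonymous-codon right inverse of translation", {
  expect_identical(
    unname(sequences(backtranslate(nirkSet(c(m = "M"), "protein")))),
    "ATG")
  expect_identical(
    unname(sequences(backtranslate(nirkSet(c(w = "W"), "protein")))),
    "TGG")
  set.seed(3)
  prot <- nirkSet(setNames(vapply(1:5, function(i) randProtein(60), ""),
                           paste0("p", 1:5)), "protein")
  nt <- backtranslate(prot, seed = 9)
  aa_back <- vapply(sequences(nt), function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))), "")
  expect_identical(unname(aa_back), unname(sequences(prot)))
  # seed-reproducible
  expect_identical(sequences(backtranslate(prot, seed = 9)),
                   sequences(nt))
  expect_error(backtranslate(nirkSet(c(x = "MX"), "protein")),
               "back-translate")
})

test_that("planted primer sites are refound as the best site with their mismatches", {
  p <- primer("p", "ATCATGGTCCTGCCGCG", "forward")
  prot <- nirkSet(setNames(vapply(1:20, function(i) randProtein(100), ""),
                           sprintf("s%02d", 1:20)), "protein")
  nt <- backtranslate(prot, seed = 1)
  groups <- setNames(rep(c("I", "II"), 10), seqIds(nt))
  pl <- plantPrimerSites(nt, p, list(II = c(1, rep(0, 16))), groups,
                         seed = 4)
  for (k in 1:20) {
    id <- pl$truth$id[k]
    hit <- bestBindingSite(p, unname(sequences(pl$set)[id]))
    expect_equal(hit$site_start, pl$truth$scan_start[k])
    expect_equal(hit$total_mismatches, pl$truth$n_mismatches[k])
    if (pl$truth$group[k] == "II")
      expect_equal(which(hit$per_position_mismatches), 1L)
  }
  # zero-mismatch spec everywhere -> all-zero profile
  pl0 <- plantPrimerSites(nt, p, list(), groups, seed = 4)
  prof <- mismatchProfile(p, pl0$set, groups)
  expect_equal(sum(prof[paste0("pos", 1:17)]), 0)
  expect_error(
    plantPrimerSites(nt, p, list(II = rep(0.5, 5)), groups, seed = 1),
    "length")
})

test_that("inventory sampling realises marginals and planted odds ratios", {
  gf <- defaultGeneFreqs()
  gen <- generateInventory(c(p = 400L), gf, associations = list(
    list(genes = c("narG", "nrfA"), or = 0.2),
    list(genes = c("napA", "nrfA"), or = 3)), seed = 41)
  inv <- gen$inventory
  expect_true(all(inv$nirK_copies >= 1L))
  for (g in names(gf))
    expect_lt(abs(mean(inv[[g]]) - gf[[g]]),
              4 * sqrt(gf[[g]] * (1 - gf[[g]]) / 400) + 0.02)
  expect_lt(cor(inv$narG, inv$nrfA), 0)
  expect_gt(cor(inv$napA, inv$nrfA), 0)

  # invalid odds ratios and cyclic constraint graphs are rejected
  expect_error(generateInventory(c(p = 10L), c(a = 0.5, b = 0.5),
                                 list(list(genes = c("a", "b"), or = 0))))
  expect_error(generateInventory(c(p = 10L), c(a = .5, b = .5, c = .5),
    associations = list(list(genes = c("a", "b"), or = 2),
                        list(genes = c("b", "c"), or = 2),
                        list(genes = c("a", "c"), or = 2))), "forest")
})

test_that("deterministic cohort construction round-trips its specification", {
  spec <- data.frame(phylum = "P", n = 2L, n_combined = 1L)
  s <- summarizeCohort(classifyGenomes(cohortFromSummary(spec)))
  expect_equal(s$pct_combined, c(50, 50))
  expect_equal(s$pct_complete, c(100, 100))

  set.seed(55)
  spec2 <- data.frame(phylum = paste0("P", 1:6),
                      n = sample(5:40, 6), stringsAsFactors = FALSE)
  spec2$n_combined <- vapply(spec2$n, function(n) sample(0:n, 1), 0L)
  spec2$n_complete <- vapply(spec2$n, function(n) sample(0:n, 1), 0L)
  rest <- spec2$n - spec2$n_complete
  spec2$n_no_nor <- vapply(rest, function(n) sample(0:n, 1), 0L)
  spec2$n_no_nos <- rest - spec2$n_no_nor
  spec2$n_no_nor_no_nos <- 0L
  s2 <- summarizeCohort(classifyGenomes(cohortFromSummary(spec2)))
  for (i in 1:6) {
    row <- s2[s2$phylum == spec2$phylum[i], ]
    expect_equal(row$n, spec2$n[i])
    expect_equal(row$pct_combined,
                 halfUp1(100 * spec2$n_combined[i] / spec2$n[i]))
    expect_equal(row$pct_complete,
                 halfUp1(100 * spec2$n_complete[i] / spec2$n[i]))
  }
  tot <- s2[s2$phylum == "Total", ]
  expect_equal(tot$pct_combined,
               halfUp1(100 * sum(spec2$n_combined) / sum(spec2$n)))

  expect_error(cohortFromSummary(data.frame(phylum = "P", n = 2L,
                                            n_combined = 3L)), "0..n")
})
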
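test_that("degenerate primers match any base in their IUPAC sets", {
  p <- primer("p", "ATGR", "forward")
  hit <- bestBindingSite(p, "CCATGACC")
  expect_equal(hit$total_mismatches, 0L)
  expect_equal(hit$site_start, 3L)

  # verbatim site always gives zero mismatches
  set.seed(4)
  for (rep in 1:5) {
    ps <- randDNA(10)
    tmpl <- paste0(randDNA(30), ps, randDNA(30))
    expect_equal(bestBindingSite(primer("q", ps, "forward"),
                                 tmpl)$total_mismatches, 0L)
  }
  expect_error(bestBindingSite(p, "AT"), "shorter than primer")
})

test_that("3' mismatches are counted within the terminal window", {
  p <- primer("p", "ATGG", "forward")
  hit <- bestBindingSite(p, "TTTATGCTTT")
  expect_equal(hit$total_mismatches, 1L)
  expect_equal(hit$three_prime_mismatches, 1L)
  expect_equal(hit$per_position_mismatches, c(FALSE, FALSE, FALSE, TRUE))

  # widen/narrow the 3' window
  hit1 <- bestBindingSite(p, "TTTATGCTTT", three_prime_window = 1)
  expect_equal(hit1$three_prime_mismatches, 1L)
  hit0 <- bestBindingSite(primer("p", "GATG", "forward"), "TTTCATGTTT",
                          three_prime_window = 3)
  expect_equal(hit0$three_prime_mismatches, 0L)
})

test_that("best-site scan equals the exhaustive-offset oracle on random templates", {
  set.seed(8)
  for (rep in 1:12) {
    ps <- paste(sample(names(IUPAC_SETS), 8, replace = TRUE,
                       prob = c(rep(1, 4), rep(0.2, 11))), collapse = "")
    tmpl <- randDNA(60)
    got <- bestBindingSite(primer("p", ps, "forward"), tmpl)
    want <- oracleBestSite(ps, tmpl)
    expect_equal(got$site_start, want$start, info = paste(ps, tmpl))
    expect_equal(got$total_mismatches, want$mismatches)
  }
})

test_that("reverse primers are scanned against the reverse complement", {
  p <- primer("r", "ACGTAC", "reverse")
  # plant revcomp(ACGTAC) = GTACGT on the given strand
  tmpl <- paste0("TTTTT", "GTACGT", "AAAAA")
  hit <- bestBindingSite(p, tmpl)
  expect_equal(hit$total_mismatches, 0L)
  expect_equal(hit$strand, "reverse_complement")
  expect_equal(hit$site_start, 6L)  # symmetric template: same offset
})

test_that("mismatch profiles recover planted per-clade rates and combine by weighting", {
  p <- primer("p", "ATCATGGTCCTGCCGCG", "forward")
  n <- 60
  prot <- nirkSet(setNames(vapply(1:n, function(i) randProtein(120), ""),
                           sprintf("s%03d", 1:n)), "protein")
  nt <- backtranslate(prot, seed = 2)
  groups <- setNames(rep(c("I", "II"), each = n / 2), seqIds(nt))
  spec <- list(I = rep(0, 17),
               II = c(0.5, rep(0, 16)))  # position 1, Clade II only
  planted <- plantPrimerSites(nt, p, spec, groups, seed = 5)
  prof <- mismatchProfile(p, planted$set, groups)
  pI <- prof[prof$group == "I", ]
  pII <- prof[prof$group == "II", ]
  comb <- prof[prof$group == "combined", ]
  expect_equal(sum(pI[paste0("pos", 1:17)]), 0)
  # planted rate within 3 binomial SDs
  expect_lt(abs(pII$pos1 - 0.5), 3 * sqrt(0.25 / (n / 2)))
  expect_equal(sum(pII[paste0("pos", 2:17)]), 0)
  # combined row is the genome-count-weighted mean of the clade rows
  for (k in 1:17) {
    pc <- paste0("pos", k)
    expect_equal(comb[[pc]],
                 (pI$n * pI[[pc]] + pII$n * pII[[pc]]) / (pI$n + pII$n))
  }
})

test_that("logo information content follows the closed-form entropies", {
  ids <- paste0("s", 1:4)
  mk <- function(x) nirkSet(setNames(x, ids), "nucleotide")
  p <- primer("p", "AAAA", "forward")
  anchors <- setNames(rep(1L, 4), ids)

  # invariant columns: 2 bits
  l1 <- bindingRegionLogo(mk(rep("AAAA", 4)), p, anchors)
  expect_equal(l1$ic, rep(2, 4))
  # uniform over ACGT: 0 bits
  l2 <- bindingRegionLogo(mk(c("AAAA", "CCCC", "GGGG", "TTTT")), p,
                          anchors)
  expect_equal(l2$ic, rep(0, 4))
  expect_equal(colSums(l2$freq), rep(1, 4), ignore_attr = TRUE)
  # half A half G: 1 bit
  l3 <- bindingRegionLogo(mk(c("AAAA", "AAAA", "GGGG", "GGGG")), p,
                          anchors)
  expect_equal(l3$ic, rep(1, 4))
  # IC decreases towards the uniform distribution
  expect_true(all(l1$ic > l3$ic) && all(l3$ic > l2$ic))
})

test_that("in-silico PCR pairs forward and downstream reverse sites under the budget", {
  set.seed(123)
  fwd <- primer("f", "ATGGTCGA", "forward")
  rev <- primer("r", "GGCATTCA", "reverse")
  insert <- randDNA(500)
  tmpl <- paste0("ATGGTCGA", insert, "TGAATGCC")  # revcomp(GGCATTCA)
  amp <- inSilicoPCR(fwd, rev, tmpl)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 8 + 500 + 8)
  expect_equal(amp$start, 1L)
  expect_equal(amp$end, nchar(tmpl))

  # reverse site upstream of the forward site: no amplicon
  tmpl2 <- paste0("TGAATGCC", insert, "ATGGTCGA")
  expect_equal(nrow(inSilicoPCR(fwd, rev, tmpl2)), 0L)

  # a 3' terminal mismatch on the forward site kills the amplicon when a
  # clean 3' end is required
  tmpl3 <- paste0("ATGGTCGT", insert, "TGAATGCC")
  ampT <- inSilicoPCR(fwd, rev, tmpl3, max_mismatch = 1,
                      require_3prime_clean = TRUE)
  expect_false(any(ampT$start == 1L))  # planted 3'-dirty site excluded
  ampF <- inSilicoPCR(fwd, rev, tmpl3, max_mismatch = 1,
                      require_3prime_clean = FALSE)
  expect_true(any(ampF$start == 1L & ampF$end == nchar(tmpl3)))
})
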
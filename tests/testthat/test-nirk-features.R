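ref <- surrogateReference()
refseq <- unname(sequences(ref))
refmap <- mapToReference(ref, ref)

mutate_at <- function(s, pos, res) {
  substr(s, pos, pos) <- res
  s
}

test_that("the reference passes all nine conserved-residue rules; point mutants fail", {
  v <- validateResidues(refseq, refmap)
  expect_true(v$is_nirk)
  expect_equal(sum(v$report$pass), 9L)
  expect_setequal(v$report$position[v$report$role == "Cu_ligand"],
                  c(59, 64, 99, 100, 110, 115, 298))
  expect_setequal(v$report$position[v$report$role == "active_site"],
                  c(62, 237))

  mut <- mutate_at(refseq, 100, "S")  # Cys100 -> Ser
  vm <- validateResidues(mut, mapToReference(mut, ref))
  expect_false(vm$is_nirk)
  expect_equal(sum(vm$report$pass), 8L)
  expect_false(vm$report$pass[vm$report$position == 100])

  # X at a rule position is never accepted
  mx <- mutate_at(refseq, 237, "X")
  vx <- validateResidues(mx, mapToReference(mx, ref))
  expect_false(vx$report$pass[vx$report$position == 237])

  ala <- paste(rep("A", 375), collapse = "")
  va <- validateResidues(ala, mapToReference(ala, ref))
  expect_false(va$is_nirk)
  expect_equal(sum(va$report$pass[va$report$role == "Cu_ligand"]), 0L)
})

test_that("active-site motifs are read in reference coordinates and flag deletions", {
  expect_equal(extractMotifs(refseq, refmap)$his237_motif, "TRPHL")

  gen <- generateNirkSet(seqGenConfig(n_clade1 = 1, n_clade2 = 1, seed = 5))
  seqs <- sequences(gen$set)
  for (k in 1:2) {
    m <- mapToReference(unname(seqs[k]), ref)
    mot <- extractMotifs(unname(seqs[k]), m)
    expect_equal(mot$his237_motif, gen$truth$his237_motif[k])
    expect_true(mot$his237_defined)
  }

  # deletion spanning His237 leaves the motif undefined and flagged
  cut <- paste0(substr(refseq, 1, 233), substr(refseq, 240, 375))
  mot <- extractMotifs(cut, mapToReference(cut, ref))
  expect_true(is.na(mot$his237_motif))
  expect_false(mot$his237_defined)
})

test_that("indel calls recover the generator's planted truth table", {
  gen <- generateNirkSet(seqGenConfig(n_clade1 = 3, n_clade2 = 3,
                                      n_bacillus_loop = 2, seed = 3))
  seqs <- sequences(gen$set)
  for (k in seq_along(seqs)) {
    m <- mapToReference(unname(seqs[k]), ref)
    ind <- detectIndels(unname(seqs[k]), m)
    tr <- gen$truth[k, ]
    expect_equal(ind$present[ind$label == "linker"], tr$linker_deleted)
    expect_equal(ind$present[ind$label == "tower"], tr$tower_deleted)
    expect_equal(ind$present[ind$label == "bacillus_loop"],
                 tr$bacillus_loop)
    if (tr$clade == "II") {
      expect_equal(ind$observed_length[ind$label == "linker"], 7L)
      expect_equal(ind$observed_length[ind$label == "tower"], 7L)
    } else {
      expect_equal(sum(ind$observed_length[ind$kind == "deletion"]), 0L)
    }
    if (tr$bacillus_loop)
      expect_equal(ind$observed_length[ind$label == "bacillus_loop"], 10L)
  }
})

test_that("clade assignment follows the two diagnostic deletions, with an explicit fallback", {
  calls <- detectIndels(refseq, refmap)
  expect_equal(assignClade(calls), "I")
  calls$present[calls$label %in% c("linker", "tower")] <- TRUE
  expect_equal(assignClade(calls), "II")
  calls$present[calls$label == "tower"] <- FALSE
  expect_equal(assignClade(calls), "unclassified")
})

test_that("domain extensions are found only in the declared overhang zones", {
  set.seed(21)
  heme <- paste0("Q", "C", "AD", "CH", randProtein(50), "M", "K")
  cupr <- paste0("E", "C", randProtein(4), "H", randProtein(4), "M", "D")

  t1 <- paste0(refseq, heme)
  e1 <- detectExtensions(t1, mapToReference(t1, ref))
  expect_true(e1$heme_c_found)
  expect_equal(e1$heme_c_offset, 2L)  # first C of the domain
  expect_false(e1$cupredoxin_found)
  expect_equal(e1$c_overhang_len, nchar(heme))

  t2 <- paste0(cupr, refseq)
  e2 <- detectExtensions(t2, mapToReference(t2, ref))
  expect_true(e2$cupredoxin_found)
  expect_false(e2$heme_c_found)

  # an overhang with no Cys cannot match either template
  t3 <- paste0(refseq, gsub("C", "A", randProtein(70)))
  e3 <- detectExtensions(t3, mapToReference(t3, ref))
  expect_false(e3$heme_c_found)

  # no overhang, no hits, even though the core contains C/H/M residues
  e4 <- detectExtensions(refseq, refmap)
  expect_false(e4$heme_c_found)
  expect_false(e4$cupredoxin_found)
  expect_equal(e4$n_overhang_len + e4$c_overhang_len, 0L)
})

test_that("redundancy filtering drops only same-species identical duplicates", {
  res <- c(a2 = "MAHCK", a1 = "MAHCK", b1 = "MAHCK", c1 = "MAHCA",
           c2 = "MAHCC")
  meta <- data.frame(
    id = names(res),
    species = c("Bacillus azotoformans", "Bacillus azotoformans",
                "Shewanella loihica", "Jonesia denitrificans",
                "Jonesia denitrificans"),
    strain = paste0("s", 1:5), phylum = "x")
  set <- nirkSet(res, "protein", meta)
  out <- filterRedundant(set)
  # same species + identical sequence: keep lexicographically smallest id
  expect_setequal(seqIds(out$set), c("a1", "b1", "c1", "c2"))
  expect_equal(out$removed$id, "a2")
  expect_equal(out$removed$duplicate_of, "a1")
})

test_that("group similarity uses pairwise deletion and matches a brute-force recount", {
  expect_equal(groupSimilarity(c(x = "AAAA", y = "AAAA"))$overall, 100)
  expect_equal(groupSimilarity(c(x = "AAAA", y = "AATT"))$overall, 50)
  # gapped columns are excluded pair by pair
  expect_equal(groupSimilarity(c(x = "AA-A", y = "AATA"))$overall, 100)

  set.seed(9)
  rows <- vapply(1:5, function(i) {
    s <- strsplit(randProtein(40), "")[[1]]
    s[sample(40, 5)] <- "-"
    paste(s, collapse = "")
  }, "")
  names(rows) <- paste0("r", 1:5)
  got <- groupSimilarity(rows, setNames(rep("g1", 5), names(rows)))
  expect_equal(got$overall, oraclePairwiseIdentity(rows))
  expect_equal(got$groups$mean_identity[1], oraclePairwiseIdentity(rows))
  expect_true(got$overall >= 0 && got$overall <= 100)

  # permutation invariance
  perm <- rows[c(3, 1, 5, 2, 4)]
  expect_equal(groupSimilarity(perm)$overall, got$overall)

  # singleton group flagged undefined
  g2 <- groupSimilarity(rows, setNames(c("a", rep("b", 4)), names(rows)))
  expect_false(g2$groups$defined[g2$groups$group == "a"])
})

test_that("copy counting reports the multi-copy genome fraction", {
  g <- c(s1 = "G1", s2 = "G1", s3 = "G2")
  cc <- countCopies(names(g), g)
  expect_equal(unname(cc$counts[c("G1", "G2")]), c(2L, 1L))
  expect_equal(cc$multi_copy_fraction, 0.5)
  expect_equal(countCopies("s3", g)$multi_copy_fraction, 0)

  gen <- generateNirkSet(seqGenConfig(n_clade1 = 60, n_clade2 = 60,
                                      multi_copy_fraction = 0.3, seed = 2))
  cc2 <- countCopies(gen$truth$id,
                     setNames(gen$truth$genome_id, gen$truth$id))
  # recovered fraction within binomial error of the configured rate
  n <- length(cc2$counts)
  expect_lt(abs(cc2$multi_copy_fraction - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})
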
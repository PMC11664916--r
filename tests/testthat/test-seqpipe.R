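test_that("pairwise identity handles the elementary cases", {
  expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwiseIdentity("AAAA", "AAAT"), 75)
  ## X never counts as a match
  expect_lt(pairwiseIdentity("AXAX", "AXAX"), 100)
})

test_that("identity is symmetric and the aligner matches an independent NW", {
  set.seed(51)
  for (i in 1:6) {
    a <- paste(sample(catalocavity:::.AA20, 60, replace = TRUE),
               collapse = "")
    b <- paste(sample(catalocavity:::.AA20, sample(40:70, 1),
                      replace = TRUE), collapse = "")
    expect_identical(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
    ## optimal global affine-gap score against Biostrings' aligner with
    ## the same scoring scheme (gap of length L costs 11 + L)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(alignPair(a, b)$score, ref)
  }
})

test_that("BLAST hit filtering applies the 30/80/80 rule inclusively", {
  hits <- data.frame(
    query_id = "REF", subject_id = c("a", "b", "c", "d"),
    pct_identity = c(45, 29.9, 30, 45),
    qcov = c(85, 99, 80, 79.9), scov = c(82, 99, 80, 99))
  kept <- filterHits(hits)
  expect_equal(kept$subject_id, c("a", "c"))
  ## idempotent and order-preserving
  expect_identical(filterHits(kept), kept)
  ## monotone in both thresholds
  expect_lte(nrow(filterHits(hits, minIdentity = 40)), nrow(kept))
  expect_lte(nrow(filterHits(hits, minCov = 90)), nrow(kept))
})

test_that("planted BLAST tables are filtered to exactly the planted rows", {
  bt <- makeBlastTable(seed = 52, nHits = 50, nPass = 23)
  kept <- filterHits(bt$hits)
  expect_equal(nrow(kept), 23)
  expect_setequal(kept$subject_id, bt$manifest$passIds)
})

test_that("the BLAST reader computes coverages when columns are absent", {
  bt <- makeBlastTable(seed = 53, nHits = 10, nPass = 5)
  f14 <- tempfile(); f12 <- tempfile()
  write.table(bt$hits, f14, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  rt <- readBlastTable(f14)
  expect_equal(rt$qcov, bt$hits$qcov)
  expect_equal(rt$scov, bt$hits$scov)
  ## 12-column variant: coverage from spans and lengths
  write.table(bt$hits[, 1:12], f12, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(readBlastTable(f12), class = "catalocavity_value_error")
  rt12 <- readBlastTable(f12, qlen = 200, slen = 400)
  expect_equal(rt12$qcov, 100 * (bt$hits$qend - bt$hits$qstart + 1) / 200)
  expect_equal(rt12$scov, 100 * (bt$hits$send - bt$hits$sstart + 1) / 400)
})

test_that("greedy clustering covers trivial and degenerate cutoffs", {
  seqs <- c(s1 = "MKVLITAAAG", s2 = "MKVLITAAAG", s3 = "MKVLITAAAG")
  cs <- greedyCluster(seqs)
  expect_length(clusters(cs), 1L)
  expect_setequal(clusters(cs)[[1]], names(seqs))
  ## an unattainable cutoff puts every sequence in its own cluster
  cs2 <- greedyCluster(c(seqs, s4 = "WWWWYYYYFF"), cutoff = 101)
  expect_length(clusters(cs2), 4L)
})

test_that("greedy clustering recovers planted families exactly", {
  fam <- makeSequenceFamilies(seed = 54, nFamilies = 5,
                              membersPerFamily = 10)
  cs <- greedyCluster(fam$sequences, cutoff = 70)
  expect_length(clusters(cs), 5L)
  got <- setNames(rep(names(clusters(cs)), lengths(clusters(cs))),
                  unlist(clusters(cs)))
  truth <- fam$manifest$family
  expect_equal(mclust::adjustedRandIndex(got[names(truth)], truth), 1.0)
  ## partition property: disjoint cover, every member close to its rep
  expect_setequal(unlist(clusters(cs)), names(fam$sequences))
  for (rep_id in representatives(cs))
    for (m in clusters(cs)[[rep_id]])
      expect_gte(pairwiseIdentity(fam$sequences[[rep_id]],
                                  fam$sequences[[m]]), 70)
})

test_that("conserved-arginine filter keeps exactly the planted sequences", {
  con <- makeSequenceFamilies(seed = 55, nFamilies = 20,
                              membersPerFamily = 1,
                              argConservedFraction = 0.6)
  out <- conservedResidueFilter(con$sequences, con$reference)
  truth <- con$manifest$argConserved[out$reports$sequence_id]
  expect_equal(out$reports$has_arg_equivalent, unname(truth))
  expect_setequal(names(out$kept), names(which(con$manifest$argConserved)))
  ## the reference itself always passes at its own position
  self <- conservedResidueFilter(con$reference, con$reference)
  expect_true(self$reports$has_arg_equivalent)
  expect_equal(self$reports$arg_column_residue, "R")
  expect_equal(self$reports$cys432_equivalent, "C")
  expect_equal(self$reports$tyr466_equivalent, "Y")
  ## a lysine at the mapped column fails the arginine requirement
  expect_true(any(out$reports$arg_column_residue[
    !out$reports$has_arg_equivalent] == "K"))
})

test_that("conserved-residue filter validates the reference position", {
  seqs <- c(rep1 = "MKVLIT")
  expect_error(conservedResidueFilter(seqs, c(REF = "MKVLIT"),
                                      refPos = 10),
               class = "catalocavity_value_error")
})

test_that("FASTA io round-trips ids and sequences", {
  fam <- makeSequenceFamilies(seed = 56, nFamilies = 2,
                              membersPerFamily = 2, refLength = 480)
  f <- tempfile(fileext = ".fasta")
  writeFastaAA(fam$sequences, f)
  back <- readFastaAA(f)
  expect_identical(back, fam$sequences)
})
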
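test_that("global alignment reproduces simple reference cases", {
  s <- simpleScheme()
  perfect <- globalAlign("AAG", "AAG", s)
  expect_equal(alignmentScore(perfect), 3)
  expect_equal(unname(alignmentRows(perfect)), c("AAG", "AAG"))

  gap <- globalAlign("AAG", "AG", s)
  expect_equal(alignmentScore(gap), 1)
  expect_equal(ungap(gap), c(a = "AAG", b = "AG"))

  expect_error(globalAlign("", "AG", s), "non-empty")
  expect_error(globalAlign("ABX", "AG", s), "nonstandard")
})

test_that("DP score equals brute-force enumeration on random short pairs", {
  s <- simpleScheme()
  set.seed(61)
  alpha <- c("A", "C", "G", "T")
  for (i in 1:120) {
    a <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(alignmentScore(globalAlign(a, b, s)),
                 bruteAlignScore(a, b, s@matrix, 0, 1),
                 info = paste(a, b))
  }
  # and with affine penalties
  aff <- substitutionScheme("simple", gapOpen = 2, gapExtend = 0.5)
  for (i in 1:60) {
    a <- paste(sample(alpha, sample(1:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:5, 1), replace = TRUE), collapse = "")
    expect_equal(alignmentScore(globalAlign(a, b, aff)),
                 bruteAlignScore(a, b, aff@matrix, 2, 0.5),
                 info = paste("affine", a, b))
  }
})

test_that("BLOSUM62 affine scores agree with the Biostrings aligner", {
  sch <- substitutionScheme("BLOSUM62", gapOpen = 10, gapExtend = 0.5)
  set.seed(33)
  for (i in 1:10) {
    a <- paste(sample(peptidomics:::AA_STANDARD, 25, replace = TRUE), collapse = "")
    b <- paste(sample(peptidomics:::AA_STANDARD, sample(15:30, 1), replace = TRUE),
               collapse = "")
    ref <- suppressWarnings(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE))
    expect_equal(alignmentScore(globalAlign(a, b, sch)), ref,
                 tolerance = 1e-9)
  }
})

test_that("alignment rows always ungap back to their inputs", {
  s <- substitutionScheme("BLOSUM62")
  set.seed(77)
  for (i in 1:20) {
    a <- paste(sample(peptidomics:::AA_STANDARD, sample(5:40, 1), replace = TRUE), collapse = "")
    b <- paste(sample(peptidomics:::AA_STANDARD, sample(5:40, 1), replace = TRUE), collapse = "")
    al <- globalAlign(c(x = a), c(y = b), s)
    expect_equal(ungap(al), c(x = a, y = b))
    expect_equal(nchar(alignmentRows(al)[[1]]), nchar(alignmentRows(al)[[2]]))
  }
})

test_that("progressive alignment of three sequences round-trips", {
  s <- simpleScheme()
  same <- progressiveAlign(c(a = "AAGT", b = "AAGT", c = "AAGT"), s)
  expect_equal(unname(alignmentRows(same)), rep("AAGT", 3))

  tri <- progressiveAlign(c(a = "AAG", b = "AAG", c = "AG"), s)
  expect_equal(nchar(alignmentRows(tri)[[1]]), 3)
  expect_equal(sum(strsplit(alignmentRows(tri)[["c"]], "")[[1]] == "-"), 1)
  expect_equal(ungap(tri), c(a = "AAG", b = "AAG", c = "AG"))

  set.seed(55)
  for (i in 1:15) {
    seqs <- setNames(vapply(1:3, function(j)
      paste(sample(c("A","C","D","G","K","L","S","T"), sample(4:15, 1),
                   replace = TRUE), collapse = ""), character(1)),
      c("sp1", "sp2", "sp3"))
    al <- progressiveAlign(seqs, substitutionScheme("BLOSUM62"))
    expect_equal(ungap(al), seqs)
  }
  expect_error(progressiveAlign(setNames(rep("AAG", 4), paste0("s", 1:4)), s),
               "2 or 3")
})

test_that("peptide regions merge overlapping and adjacent intervals", {
  r <- peptideRegions(data.frame(start = c(1, 5), end = c(10, 15)))
  expect_equal(r$regions, data.frame(start = 1L, end = 15L))
  expect_equal(r$total_residues, 15L)

  adj <- peptideRegions(data.frame(start = c(1, 11), end = c(10, 20)))
  expect_equal(nrow(adj$regions), 1L)
  expect_equal(adj$total_residues, 20L)

  single <- peptideRegions(data.frame(start = 7, end = 13))
  expect_equal(single$total_residues, 7L)

  # idempotent and order-independent
  set.seed(14)
  iv <- data.frame(start = sample(1:50, 12, replace = TRUE))
  iv$end <- iv$start + sample(0:10, 12, replace = TRUE)
  a <- peptideRegions(iv)
  b <- peptideRegions(iv[sample(nrow(iv)), ])
  cc <- peptideRegions(a$regions)
  expect_equal(a$regions, b$regions)
  expect_equal(a$regions, cc$regions)
})

test_that("region identity separates peptide-covered from whole-protein identity", {
  aln <- new("MultiAlignment",
             rows = c(y = "AAG", m = "AAG", h = "ACG"), score = NA_real_)
  ri <- regionIdentity(aln, "y", data.frame(start = 1, end = 2))
  expect_equal(ri$identity_whole, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(ri$identity_within_peptides, 50)
  expect_equal(ri$peptide_region_length, 2L)
  expect_equal(ri$protein_length, 3L)

  ident <- new("MultiAlignment",
               rows = c(y = "KLMNP", m = "KLMNP", h = "KLMNP"), score = NA_real_)
  ri2 <- regionIdentity(ident, "y", data.frame(start = 2, end = 4))
  expect_equal(ri2$identity_whole, 100)
  expect_equal(ri2$identity_within_peptides, 100)

  # a gap in any row is non-identical; denominator is reference residues
  gaps <- new("MultiAlignment",
              rows = c(y = "KLMN", m = "K-MN", h = "KLMN"), score = NA_real_)
  ri3 <- regionIdentity(gaps, "y", data.frame(start = 1, end = 4))
  expect_equal(ri3$identity_whole, 75)
  expect_equal(ri3$identity_whole, ri3$identity_within_peptides)  # whole-protein region

  disjoint <- new("MultiAlignment",
                  rows = c(y = "KKK", m = "RRR", h = "HHH"), score = NA_real_)
  expect_equal(regionIdentity(disjoint, "y",
                              data.frame(start = 1, end = 3))$identity_whole, 0)
  expect_error(regionIdentity(aln, "nope", data.frame(start = 1, end = 2)),
               "not in alignment")
  expect_error(regionIdentity(aln, "y", data.frame(start = 1, end = 9)),
               "within the reference")
})

test_that("conservation report assembles one row per ortholog set", {
  sets <- list(
    s1 = c(y = "MKAVLLGGK", m = "MKAVLLGGK", h = "MKAVLAGGK"),
    s2 = c(y = "DDEEKK", h = "DDEEKK"))
  regions <- list(s1 = data.frame(start = 1, end = 4),
                  s2 = data.frame(start = 1, end = 2))
  rep <- conservationReport(sets, regions, substitutionScheme("BLOSUM62"))
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$peptide_aa, c(4L, 2L))
  expect_equal(rep$identity_within[1], 100)
  expect_equal(rep$identity_whole[2], 100)
  expect_true(rep$identity_whole[1] < 100)
})
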
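test_that("amino-acid composition counts residues over unique peptides", {
  one <- aaComposition("AAAA")
  expect_equal(one$percent[one$residue == "A"], 100)
  four <- aaComposition("ACDE")
  expect_equal(four$percent[four$residue %in% c("A", "C", "D", "E")],
               rep(25, 4))
  expect_equal(sum(four$fraction), 1)
  # dedupe flag: same sequence twice counts once by default
  dup <- aaComposition(c("AC", "AC", "GG"))
  expect_equal(attr(dup, "total"), 4L)
  all_det <- aaComposition(c("AC", "AC", "GG"), dedupe = FALSE)
  expect_equal(attr(all_det, "total"), 6L)
  expect_error(aaComposition(character(0)), "no peptides")
})

test_that("percent tables sum to 100 within rounding and fractions to 1", {
  set.seed(11)
  peps <- vapply(1:40, function(i)
    paste(sample(c("A","D","G","K","L","S","V"), sample(7:20, 1), replace = TRUE),
          collapse = ""), character(1))
  for (tab in list(aaComposition(peps), ntermResidueFreq(peps))) {
    expect_equal(sum(tab$fraction), 1, tolerance = 1e-12)
    expect_true(abs(sum(tab$percent) - 100) <= 0.1)
  }
})

test_that("composition of a simulated peptidome recovers the generator frequencies", {
  freqs <- setNames(rep(0.05, 20), c("A","C","D","E","F","G","H","I","K","L",
                                     "M","N","P","Q","R","S","T","V","W","Y"))
  # uniform abundance and a large protein pool so peptides draw nearly
  # independent stretches of sequence (a multinomial-regime check)
  cfg <- simConfig(seed = 20, nProteins = 400, nPeptides = 3200,
                   residueFreqs = freqs, theta = 0, abundanceSdlog = 0,
                   p1Weights = c(ACIDIC = 1, BASIC = 1, HYDROPHOBIC = 1,
                                 PRO = 1, OTHER = 1))
  st <- simulateStudy(cfg)
  comp <- aaComposition(st$peptides, dedupe = FALSE)
  total <- attr(comp, "total")
  expect_gt(total, 40000)
  se <- sqrt(0.05 * 0.95 / total)
  off <- abs(comp$fraction - 0.05)
  # forced initiator Met slightly inflates M; allow it, check the rest
  expect_true(all(off[comp$residue != "M"] <= 3 * se + 0.002))
})

test_that("N-terminal residue frequencies count first residues", {
  nf <- ntermResidueFreq(c("AK", "AG", "GV"))
  expect_equal(nf$count[nf$residue == "A"], 2L)
  expect_equal(nf$count[nf$residue == "G"], 1L)
  expect_equal(round(nf$percent[nf$residue == "A"], 1), 66.7)
  single <- ntermResidueFreq("KAV")
  expect_equal(single$percent[single$residue == "K"], 100)
})

test_that("acetyl fraction handles tables, vectors, and empties", {
  tbl <- data.frame(sequence = c("AK", "GV", "LL", "MM"),
                    n_acetyl = c(1, 0, 0, 0))
  expect_equal(acetylFraction(tbl), 0.25)
  expect_equal(acetylFraction(logical(0)), 0)
  expect_equal(acetylFraction(c(FALSE, FALSE)), 0)
})

test_that("size statistics report mean, median and window fraction", {
  s <- sizeStats(c(1000, 2000, 3000))
  expect_equal(s$mean_mass, 2000)
  expect_equal(s$median_mass, 2000)
  expect_equal(s$fraction_in_window, 1)
  s2 <- sizeStats(c(800, 1000, 2000, 5000))
  expect_equal(s2$median_mass, 1500)          # even n: mean of middle two
  expect_equal(s2$fraction_in_window, 0.5)
  one <- sizeStats(1523)
  expect_equal(one$mean_mass, one$median_mass)
  expect_error(sizeStats(numeric(0)), "non-empty")
})

test_that("terminal tally merges the N-terminal classes", {
  cls <- factor(c("N_TERMINAL_WITH_MET", "C_TERMINAL", "INTERNAL", "INTERNAL"),
                levels = peptidomics:::TERMINAL_CLASSES)
  tt <- terminalTally(cls)
  expect_equal(tt$denominator, 4L)
  m <- tt$merged
  expect_equal(m$percent[m$class == "N-term"], 25)
  expect_equal(m$percent[m$class == "C-term"], 25)
  expect_equal(m$percent[m$class == "internal"], 50)
  expect_equal(sum(tt$by_class$count), 4L)

  allInt <- terminalTally(factor(rep("INTERNAL", 10),
                                 levels = peptidomics:::TERMINAL_CLASSES))
  expect_equal(allInt$merged$percent, c(0, 0, 100))

  merged3 <- terminalTally(factor(c("N_TERMINAL_MET_REMOVED", "MATURE_N_TERMINAL"),
                                  levels = peptidomics:::TERMINAL_CLASSES))
  expect_equal(merged3$merged$count[1], 2L)   # both count as N-term
})

test_that("cleavage tallies report per-site and per-peptide denominators", {
  prot <- Proteome(c(H1 = "GKAVSYAGT"))
  m <- mapPeptides("AVSYA", prot)           # upstream K, downstream G
  s <- cleavageSites(m, prot)
  ct <- cleavageTally(s)
  ps <- ct$per_site
  expect_equal(ps$fraction[ps$category == "BASIC"], 0.5)
  expect_equal(ps$fraction[ps$category == "HYDROPHOBIC"], 0.5)
  pp <- ct$per_peptide
  expect_equal(pp$fraction[pp$category == "BASIC"], 1)
  expect_equal(pp$fraction[pp$category == "HYDROPHOBIC"], 1)
  # whole-protein peptides contribute no sites but stay in the denominator
  ct2 <- cleavageTally(s, nPeptides = 2)
  expect_equal(ct2$per_peptide$fraction[pp$category == "BASIC"], 0.5)
  empty <- cleavageTally(s[0, ], nPeptides = 0)
  expect_equal(empty$n_sites, 0L)
  expect_equal(sum(empty$per_site$count), 0L)
})

test_that("category tallies count each protein once with an unknown bucket", {
  prot <- testProteome()
  loc <- tallyByCategory(prot, "location")
  expect_equal(attr(loc, "denominator"), 5L)
  expect_equal(loc$count[loc$category == "cytosol"], 2L)
  expect_equal(loc$count[loc$category == "unknown"], 1L)
  expect_equal(sum(loc$count), 5L)
  none <- tallyByCategory(Proteome(c(A = "MKV", B = "MAV")), "function")
  expect_equal(none$percent[none$category == "unknown"], 100)
})

test_that("supplementary-style table summary computes the census bundle", {
  pep <- data.frame(
    sequence = c("MAVK", "AVKT", "TAGW", "STLP", "STLP"),
    n_acetyl = c(1, 0, 0, 0, 0),
    ox_met = "",
    gene = c("G1", "G1", "G2", "G3", "G3"),
    start = c(1L, 2L, 6L, 3L, 3L),
    upstream = c("-", "M", "T", "A", "A"),
    downstream = c("T", "T", "-", "E", "E"),
    mass = c(1000, 1200, 1500, 2000, 2000),
    stringsAsFactors = FALSE)
  s <- supplementaryTableSummary(pep)
  expect_equal(s$n_peptides, 4L)                     # duplicate collapsed
  expect_equal(s$acetyl_fraction, 0.25)
  expect_equal(s$size$median_mass, 1350)
  tm <- s$terminal$merged
  expect_equal(tm$count[tm$class == "N-term"], 2L)   # MAVK + AVKT (Met removed)
  expect_equal(tm$count[tm$class == "C-term"], 1L)
  expect_equal(s$min_cover_half, 2L)
  prt <- data.frame(gene = c("G1", "G2", "G3"), length = c(100, 300, 500))
  s2 <- supplementaryTableSummary(pep, prt)
  expect_equal(s2$protein_lengths$mean_length, 300)
  expect_equal(s2$protein_lengths$median_length, 300)
})
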
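test_that("simulation is fully deterministic given seed and config", {
  cfg <- simConfig(seed = 9, nProteins = 20, nPeptides = 40)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulateStudy(cfg, d1)
  s2 <- simulateStudy(cfg, d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
  s3 <- simulateStudy(simConfig(seed = 10, nProteins = 20, nPeptides = 40))
  expect_false(identical(s1$peptides$sequence, s3$peptides$sequence))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(simulateStudy(simConfig(seed = 5, nProteins = 10, nPeptides = 10)))
  after <- runif(2)
  expect_equal(after, before[2:3])
})

test_that("proteome generation honors length bounds, initiator Met and frequencies", {
  cfg <- simConfig(seed = 4, nProteins = 60, lengthMean = 200, lengthSd = 80,
                   lengthMin = 60)
  prot <- makeProteome(cfg)
  expect_equal(length(prot), 60L)
  expect_true(all(proteinLengths(prot) >= 60))
  expect_true(all(substr(proteinSequences(prot), 1, 1) == "M"))

  # degenerate frequencies: all mass on A (after the forced Met)
  fA <- setNames(c(1, rep(0, 19)),
                 c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y"))
  pa <- makeProteome(simConfig(seed = 4, nProteins = 5, residueFreqs = fA))
  expect_true(all(grepl("^MA+$", proteinSequences(pa))))

  # multinomial check at uniform frequencies
  fU <- setNames(rep(0.05, 20), names(fA))
  pu <- makeProteome(simConfig(seed = 6, nProteins = 40, residueFreqs = fU,
                               lengthMean = 260, lengthSd = 10, lengthMin = 200))
  counts <- colSums(Biostrings::alphabetFrequency(pu@sequences)[, names(fA)])
  total <- sum(counts)
  se <- sqrt(0.05 * 0.95 / total)
  off <- abs(counts / total - 0.05)
  expect_true(all(off[names(off) != "M"] <= 3 * se + 0.002))
})

test_that("ground-truth coordinates round-trip through mapping", {
  cfg <- simConfig(seed = 12, nProteins = 30, nPeptides = 60)
  st <- simulateStudy(cfg)
  pseq <- proteinSequences(st$proteome)
  sl <- substr(pseq[st$truth$protein_id], st$truth$start, st$truth$end)
  expect_equal(unname(sl), st$truth$sequence)
  # and the emitted table is found at the recorded position by the mapper
  m <- mapPeptides(st$peptides[1:10, ], st$proteome)
  for (i in 1:10) {
    hit <- m[m$sequence == st$truth$sequence[i] &
             m$protein_id == st$truth$protein_id[i] &
             m$start == st$truth$start[i], ]
    expect_equal(nrow(hit), 1L, info = paste("peptide", i))
  }
})

test_that("terminal enrichment theta spans the design range monotonically", {
  uniW <- c(ACIDIC = 1, BASIC = 1, HYDROPHOBIC = 1, PRO = 1, OTHER = 1)
  fracs <- vapply(c(0, 0.3, 0.6, 1), function(th) {
    cfg <- simConfig(seed = 31, nProteins = 25, nPeptides = 1200, theta = th,
                     p1Weights = uniW)
    st <- simulateStudy(cfg)
    mean(st$truth$terminal)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  expect_equal(fracs[4], 1)                      # theta = 1: all terminal
  expect_lt(fracs[1], 0.1)
})

test_that("P1 weights steer the upstream flanking residue", {
  basicOnly <- c(ACIDIC = 0, BASIC = 1, HYDROPHOBIC = 0, PRO = 0, OTHER = 0)
  cfg <- simConfig(seed = 17, nProteins = 20, nPeptides = 150, theta = 0,
                   p1Weights = basicOnly)
  st <- simulateStudy(cfg)
  up <- st$peptides$upstream[st$peptides$upstream != "-"]
  expect_true(all(up %in% c("K", "R")))
})

test_that("zero-noise intensities recover every fold change exactly", {
  cfg <- simConfig(seed = 21, nProteins = 15, nPeptides = 40, noiseCv = 0,
                   foldChange = 2.5, changedFraction = 0.5)
  st <- simulateStudy(cfg)
  q <- quantifyRuns(st$intensities, st$designs, minRuns = 2)
  truth <- st$truth[!duplicated(st$truth$sequence), ]
  res <- merge(q$results, truth[, c("sequence", "true_fold")], by = "sequence")
  expect_equal(res$treated_mean, res$true_fold, tolerance = 1e-9)
  expect_equal(res$control_mean, rep(1, nrow(res)), tolerance = 1e-12)
})

test_that("peptide masses in emitted tables are computed, not simulated", {
  cfg <- simConfig(seed = 25, nProteins = 10, nPeptides = 20)
  st <- simulateStudy(cfg)
  expect_equal(st$peptides$mass,
               round(monoisotopicMass(st$peptides$sequence,
                                      nAcetyl = st$peptides$n_acetyl == 1), 5))
})
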
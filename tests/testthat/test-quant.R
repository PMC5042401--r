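d1 <- testDesign("r1")

test_that("charge-state averaging is per-channel over detected states", {
  tbl <- data.frame(run_id = "r1", sequence = "AVSK", mod_signature = "",
                    charge = c(2L, 3L),
                    D0 = c(100, 200), D3 = c(50, 150),
                    D6 = c(NA, 300), D9 = c(NA_real_, NA_real_))
  avg <- averageChargeStates(tbl)
  expect_equal(nrow(avg), 1L)
  expect_equal(avg$charge, 0L)
  expect_equal(avg$D0, 150)
  expect_equal(avg$D3, 100)
  expect_equal(avg$D6, 300)   # detected in one state only
  expect_true(is.na(avg$D9))  # ND stays ND
  one <- averageChargeStates(tbl[1, ])
  expect_equal(one$D0, 100)
  expect_error(averageChargeStates(tbl[0, ]), "no intensity")
})

test_that("relative levels normalize to the detected control mean", {
  tbl <- data.frame(run_id = "r1", sequence = "AVSK", mod_signature = "",
                    charge = 0L, D0 = 80, D3 = 120, D6 = 300, D9 = NA_real_)
  lv <- relativeLevels(tbl, d1)
  expect_equal(lv$D0, 0.8)
  expect_equal(lv$D3, 1.2)
  expect_equal(lv$D6, 3.0)
  expect_true(is.na(lv$D9))
  expect_equal(mean(c(lv$D0, lv$D3)), 1, tolerance = 1e-12)

  eq <- data.frame(run_id = "r1", sequence = "X", mod_signature = "",
                   charge = 0L, D0 = 7, D3 = 7, D6 = 7, D9 = 7)
  lveq <- relativeLevels(eq, d1)
  expect_equal(unlist(lveq[, c("D0", "D3", "D6", "D9")]),
               c(D0 = 1, D3 = 1, D6 = 1, D9 = 1))

  nc <- data.frame(run_id = "r1", sequence = "Y", mod_signature = "",
                   charge = 0L, D0 = NA_real_, D3 = NA_real_, D6 = 5, D9 = 5)
  expect_warning(lnc <- relativeLevels(nc, d1), "unquantifiable")
  expect_false(lnc$quantifiable)
  expect_true(all(is.na(lnc[, c("D0", "D3", "D6", "D9")])))
})

test_that("control self-normalization and scale invariance hold on random data", {
  set.seed(5)
  for (i in 1:25) {
    tbl <- data.frame(run_id = "r1", sequence = paste0("PEP", i),
                      mod_signature = "", charge = 0L,
                      D0 = runif(1, 10, 1e5), D3 = runif(1, 10, 1e5),
                      D6 = runif(1, 10, 1e5), D9 = runif(1, 10, 1e5))
    lv <- relativeLevels(tbl, d1)
    expect_equal((lv$D0 + lv$D3) / 2, 1, tolerance = 1e-12)
    cc <- runif(1, 1e-3, 1e3)
    tbl2 <- tbl
    for (ch in c("D0", "D3", "D6", "D9")) tbl2[[ch]] <- tbl2[[ch]] * cc
    lv2 <- relativeLevels(tbl2, d1)
    expect_equal(unlist(lv2[, c("D0", "D3", "D6", "D9")]),
                 unlist(lv[, c("D0", "D3", "D6", "D9")]), tolerance = 1e-12)
  }
})

.mkLevels <- function(ctrl, trt, runs = c("r1", "r2"), seqn = "AVSK") {
  # two runs, two control + two treated ratios each, interleaved
  stopifnot(length(ctrl) == 4, length(trt) == 4)
  data.frame(run_id = rep(runs, each = 1),
             sequence = seqn, mod_signature = "", charge = 0L,
             D0 = ctrl[c(1, 3)], D3 = ctrl[c(2, 4)],
             D6 = trt[c(1, 3)], D9 = trt[c(2, 4)],
             quantifiable = TRUE)
}

test_that("pooled Student's t matches the hand formula and reference example", {
  designs <- list(testDesign("r1"), testDesign("r2"))
  # reference example with two ratios per group, built by marking one
  # channel ND per run
  lv <- data.frame(run_id = c("r1", "r2"), sequence = "AVSK",
                   mod_signature = "", charge = 0L,
                   D0 = c(0.9, 1.1), D3 = NA_real_,
                   D6 = c(1.9, 2.1), D9 = NA_real_, quantifiable = TRUE)
  res <- poolAndTest(lv, designs, minRuns = 2)
  orc <- pooledT(c(1.9, 2.1), c(0.9, 1.1))
  expect_equal(res$t, orc$t, tolerance = 1e-6)
  expect_equal(res$t, 7.0710678, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  expect_equal(res$p_value, 0.0194, tolerance = 1e-2)
  expect_equal(res$tier, "P05")
  expect_equal(res$fold_class, "WITHIN")   # mean 2.0 is not > 2
  expect_equal(res$n_control, 2L)
  expect_equal(res$n_treated, 2L)
  expect_equal(res$control_mean, 1.0)
  expect_equal(res$treated_sem, sd(c(1.9, 2.1)) / sqrt(2))
})

test_that("pooling accumulates replicates across runs as in n = 8 designs", {
  designs <- list(testDesign("r1"), testDesign("r2"))
  lv <- .mkLevels(c(0.9, 1.1, 0.8, 1.2), c(2.5, 2.0, 3.0, 2.6))
  res <- poolAndTest(lv, designs, minRuns = 2)
  expect_equal(res$n_control, 4L)
  expect_equal(res$n_treated, 4L)
  orc <- pooledT(c(2.5, 3.0, 2.0, 2.6), c(0.9, 0.8, 1.1, 1.2))
  expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  expect_equal(res$df, 6)
  expect_equal(res$fold_class, "UP_2X")
})

test_that("degenerate and under-replicated cases are flagged, not infinite", {
  designs <- list(testDesign("r1"), testDesign("r2"))
  lv <- .mkLevels(c(1, 1, 1, 1), c(1, 1, 1, 1))
  res <- poolAndTest(lv, designs, minRuns = 2)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$tier, "NS")

  lv2 <- .mkLevels(c(1, 1, 1, 1), c(2, 2, 2, 2))
  res2 <- poolAndTest(lv2, designs, minRuns = 2)
  expect_equal(res2$flag, "degenerate")
  expect_true(is.na(res2$p_value))

  res3 <- poolAndTest(lv2, designs, minRuns = 3)   # only 2 runs available
  expect_equal(res3$flag, "below_min_runs")
  expect_true(is.na(res3$p_value))
  expect_equal(res3$tier, "NS")
})

test_that("rank plot data is an ascending, stable ranking", {
  rp <- rankPlotData(c(2.0, 0.5, 1.0))
  expect_equal(rp$ratio, c(0.5, 1.0, 2.0))
  expect_equal(rp$rank, 1:3)
  expect_equal(rankPlotData(rep(3, 5))$rank, 1:5)
  expect_equal(nrow(rankPlotData(numeric(0))), 0L)
  set.seed(9)
  x <- rlnorm(1000)
  rp2 <- rankPlotData(x)
  expect_equal(nrow(rp2), 1000L)
  expect_true(!is.unsorted(rp2$ratio))
})

test_that("fold-change tally uses strict thresholds", {
  ft <- foldChangeTally(c(0.4, 3.0, 1.0))
  expect_equal(unname(ft$counts), c(1, 1, 1))
  expect_equal(ft$fraction_changed, 2 / 3)
  expect_equal(unname(foldChangeTally(2.0)$counts["WITHIN"]), 1)   # exactly 2 is WITHIN
  expect_equal(unname(foldChangeTally(0.5)$counts["WITHIN"]), 1)
  z <- foldChangeTally(numeric(0))
  expect_equal(unname(z$counts), c(0, 0, 0))
  expect_equal(z$fraction_changed, 0)
})
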
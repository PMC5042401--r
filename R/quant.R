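# Relative quantification from multiplexed label intensities.
#
# Within one LC-MS run every channel carries one biological replicate.
# A peptide's relative level in a channel is its (charge-state-averaged)
# peak intensity divided by the mean intensity over the detected CONTROL
# channels of the same run, so the control ratios of a run average to 1
# by construction and ratios are comparable across runs. Pooled control
# and treated ratios are then compared per peptide with Student's
# (pooled-variance) t-test.

.channelCols <- function(tbl) {
  setdiff(names(tbl), c("run_id", "sequence", "mod_signature", "charge",
                        "quantifiable"))
}

#' Average peak intensities over charge states
#'
#' A peptide observed at several charge states in one run is collapsed to
#' a single observation: per channel, the arithmetic mean over the charge
#' states in which that channel was detected. The combined row carries
#' the sentinel charge 0.
#'
#' @param tbl intensity data.frame (see [readIntensityTable()]); may
#'   contain many peptides and runs.
#' @return data.frame with one row per (run, sequence, modification
#'   signature), charge 0.
#' @examples
#' tbl <- data.frame(run_id = "r1", sequence = "AVSK", mod_signature = "",
#'                   charge = 2:3, D0 = c(100, 200), D3 = c(50, 150))
#' averageChargeStates(tbl)
#' @export
averageChargeStates <- function(tbl) {
  if (!nrow(tbl)) stop("no intensity observations supplied")
  chans <- .channelCols(tbl)
  key <- interaction(tbl$run_id, tbl$sequence, tbl$mod_signature,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(tbl)), key)
  rows <- lapply(idx, function(i) {
    out <- tbl[i[1], c("run_id", "sequence", "mod_signature"), drop = FALSE]
    out$charge <- 0L
    for (ch in chans) {
      v <- tbl[[ch]][i]
      out[[ch]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$run_id, out$sequence, out$mod_signature), , drop = FALSE]
}

#' Relative levels: ratio of each channel to the control mean
#'
#' For each observation of the design's run, every detected channel's
#' intensity is divided by the mean intensity over the detected control
#' channels. Channels not detected stay NA ("ND"). Observations with no
#' detected control channel cannot be normalized and are flagged
#' \code{quantifiable = FALSE} (ratios all NA).
#'
#' @param tbl charge-state-averaged intensity data.frame.
#' @param design the \linkS4class{ChannelDesign} of the run.
#' @return data.frame with the channel columns replaced by ratios, plus
#'   a logical \code{quantifiable} column.
#' @examples
#' d <- channelDesign("r1", c("D0", "D3", "D6", "D9"),
#'                    c("CONTROL", "CONTROL", "TREATED", "TREATED"))
#' tbl <- data.frame(run_id = "r1", sequence = "AVSK", mod_signature = "",
#'                   charge = 0, D0 = 80, D3 = 120, D6 = 300, D9 = NA)
#' relativeLevels(tbl, d)
#' @export
relativeLevels <- function(tbl, design) {
  tbl <- tbl[tbl$run_id == designRunId(design), , drop = FALSE]
  chans <- intersect(designChannels(design), names(tbl))
  miss <- setdiff(designChannels(design), names(tbl))
  if (length(miss))
    stop("intensity table lacks channel column(s): ", paste(miss, collapse = ", "))
  ctrl <- controlChannels(design)
  cmat <- as.matrix(tbl[, ctrl, drop = FALSE])
  cmean <- rowMeans(cmat, na.rm = TRUE)          # NaN when no control detected
  quantifiable <- !is.nan(cmean) & cmean > 0
  for (ch in chans)
    tbl[[ch]] <- ifelse(quantifiable, tbl[[ch]] / cmean, NA_real_)
  tbl$quantifiable <- quantifiable
  if (any(!quantifiable))
    warning(sum(!quantifiable), " observation(s) in run ", designRunId(design),
            " had no detected control channel and were flagged unquantifiable")
  tbl
}

.tierOf <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  tiers <- sort(tiers, decreasing = TRUE)
  ifelse(is.na(p), "NS",
         ifelse(p < tiers[3], "P001",
                ifelse(p < tiers[2], "P01",
                       ifelse(p < tiers[1], "P05", "NS"))))
}

.foldClassOf <- function(m, threshold = 2) {
  ifelse(is.na(m), NA_character_,
         ifelse(m > threshold, "UP_2X",
                ifelse(m < 1 / threshold, "DOWN_2X", "WITHIN")))
}

#' Pool replicate ratios across runs and test treated vs control
#'
#' Relative levels from several runs are pooled per peptide: all detected
#' control-channel ratios form the control group, all detected
#' treated-channel ratios the treated group. Groups are compared with a
#' two-sided two-sample Student's t-test (pooled variance,
#' df = n1 + n2 - 2). Peptides quantifiable in fewer than \code{minRuns}
#' runs are kept but flagged \code{below_min_runs} and not tested.
#'
#' Degenerate variance cases on small fixtures are resolved explicitly:
#' both groups constant and equal means gives t = 0 / p = 1 (NS); both
#' constant but unequal means is flagged \code{degenerate} with p absent.
#'
#' A Benjamini-Hochberg adjusted column (\code{p_bh}) is reported
#' alongside the raw p-values; the significance tiers follow the raw
#' p-values, matching how such tables are conventionally reported.
#'
#' @param levels data.frame of relative levels (rows from
#'   [relativeLevels()], possibly several runs bound together).
#' @param designs named list of \linkS4class{ChannelDesign}, keyed by or
#'   containing the run ids appearing in \code{levels}.
#' @param minRuns minimum number of runs a peptide must be quantifiable
#'   in to enter pooled testing (default 3).
#' @param tiers significance thresholds, descending (default
#'   0.05/0.01/0.001).
#' @param foldThreshold fold-change cutoff; treated means strictly above
#'   it (or strictly below its reciprocal) are classed UP_2X / DOWN_2X.
#' @return data.frame with one row per peptide: pooled means, SEMs,
#'   replicate counts, t, df, p_value, p_bh, tier, fold_class, flag.
#' @export
poolAndTest <- function(levels, designs, minRuns = 3,
                        tiers = c(0.05, 0.01, 0.001), foldThreshold = 2) {
  if (!nrow(levels)) stop("no relative levels supplied")
  runIds <- vapply(designs, designRunId, character(1))
  names(designs) <- runIds
  bad <- setdiff(unique(levels$run_id), runIds)
  if (length(bad)) stop("no design for run(s): ", paste(bad, collapse = ", "))
  if (!"quantifiable" %in% names(levels)) levels$quantifiable <- TRUE

  key <- interaction(levels$sequence, levels$mod_signature,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(levels)), key)
  rows <- lapply(idx, function(i) {
    sub <- levels[i, , drop = FALSE]
    ctrl <- numeric(0); trt <- numeric(0)
    nRuns <- 0L
    for (j in seq_len(nrow(sub))) {
      if (!sub$quantifiable[j]) next
      d <- designs[[sub$run_id[j]]]
      cc <- intersect(controlChannels(d), names(sub))
      tc <- intersect(treatedChannels(d), names(sub))
      cv <- unlist(sub[j, cc]); cv <- cv[!is.na(cv)]
      tv <- unlist(sub[j, tc]); tv <- tv[!is.na(tv)]
      if (length(cv)) nRuns <- nRuns + 1L
      ctrl <- c(ctrl, cv); trt <- c(trt, tv)
    }
    out <- data.frame(
      sequence = sub$sequence[1], mod_signature = sub$mod_signature[1],
      control_mean = if (length(ctrl)) mean(ctrl) else NA_real_,
      control_sem = if (length(ctrl) > 1) sd(ctrl) / sqrt(length(ctrl)) else NA_real_,
      n_control = length(ctrl),
      treated_mean = if (length(trt)) mean(trt) else NA_real_,
      treated_sem = if (length(trt) > 1) sd(trt) / sqrt(length(trt)) else NA_real_,
      n_treated = length(trt),
      n_runs = nRuns,
      t = NA_real_, df = NA_real_, p_value = NA_real_,
      flag = "", stringsAsFactors = FALSE
    )
    if (nRuns < minRuns) {
      out$flag <- "below_min_runs"
      return(out)
    }
    if (length(ctrl) < 2 || length(trt) < 2) {
      out$flag <- "insufficient_replicates"
      return(out)
    }
    eps <- 1e-10 * max(1, abs(mean(ctrl)), abs(mean(trt)))
    if (sd(ctrl) <= eps && sd(trt) <= eps) {
      if (abs(mean(ctrl) - mean(trt)) <= eps) {
        out$t <- 0; out$df <- length(ctrl) + length(trt) - 2; out$p_value <- 1
      } else out$flag <- "degenerate"
      return(out)
    }
    tt <- tryCatch(t.test(trt, ctrl, var.equal = TRUE), error = function(e) NULL)
    if (is.null(tt)) {                     # constant data at machine precision
      out$flag <- "degenerate"
      return(out)
    }
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  res$tier <- .tierOf(res$p_value, tiers)
  res$fold_class <- .foldClassOf(res$treated_mean, foldThreshold)
  res[order(res$sequence, res$mod_signature), , drop = FALSE]
}

#' Rank-plot data for a set of ratios
#'
#' Sorts finite ratios ascending (stable: ties keep input order) and
#' attaches ranks 1..n, the form in which relative-level distributions
#' are conventionally visualized.
#'
#' @param ratios numeric vector; NA (ND) entries are dropped.
#' @param group optional parallel grouping vector carried through.
#' @return data.frame with columns \code{rank}, \code{ratio} (and
#'   \code{group} if given).
#' @export
rankPlotData <- function(ratios, group = NULL) {
  keep <- is.finite(ratios)
  r <- ratios[keep]
  if (!length(r))
    return(data.frame(rank = integer(), ratio = numeric()))
  ord <- order(r)  # radix sort: stable for ties
  out <- data.frame(rank = seq_along(r), ratio = r[ord])
  if (!is.null(group)) out$group <- group[keep][ord]
  out
}

#' Tally two-fold changes
#'
#' Counts ratios strictly above the threshold (UP_2X), strictly below its
#' reciprocal (DOWN_2X), and within (a ratio of exactly 2 is WITHIN:
#' thresholds are strict).
#'
#' @param ratios numeric vector of relative levels (NA dropped).
#' @param threshold fold-change cutoff (default 2).
#' @return list with \code{counts} (named UP_2X/DOWN_2X/WITHIN),
#'   \code{n} and \code{fraction_changed}.
#' @examples
#' foldChangeTally(c(0.4, 3.0, 1.0))
#' @export
foldChangeTally <- function(ratios, threshold = 2) {
  r <- ratios[!is.na(ratios)]
  counts <- c(UP_2X = sum(r > threshold),
              DOWN_2X = sum(r < 1 / threshold))
  counts["WITHIN"] <- length(r) - sum(counts)
  list(counts = counts, n = length(r),
       fraction_changed = if (length(r)) unname((counts["UP_2X"] + counts["DOWN_2X"]) / length(r)) else 0)
}

#' Full quantification pipeline for one or more runs
#'
#' Convenience wrapper: charge-state averaging, per-run relative levels,
#' then pooled differential testing.
#'
#' @param tbl raw intensity data.frame covering one or more runs.
#' @param designs list of \linkS4class{ChannelDesign}; runs without a
#'   design are dropped with a warning.
#' @inheritParams poolAndTest
#' @return list with \code{levels} (per-run ratios) and \code{results}
#'   (pooled differential table).
#' @export
quantifyRuns <- function(tbl, designs, minRuns = 3,
                         tiers = c(0.05, 0.01, 0.001), foldThreshold = 2) {
  runIds <- vapply(designs, designRunId, character(1))
  names(designs) <- runIds
  drop <- setdiff(unique(tbl$run_id), runIds)
  if (length(drop)) {
    warning("no channel design for run(s) ", paste(drop, collapse = ", "),
            "; excluded")
    tbl <- tbl[!tbl$run_id %in% drop, , drop = FALSE]
  }
  avg <- averageChargeStates(tbl)
  lv <- do.call(rbind, c(lapply(runIds[runIds %in% avg$run_id], function(r)
    relativeLevels(avg, designs[[r]])), list(make.row.names = FALSE)))
  list(levels = lv,
       results = poolAndTest(lv, designs, minRuns = minRuns,
                             tiers = tiers, foldThreshold = foldThreshold))
}
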
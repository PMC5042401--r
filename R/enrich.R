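# Relating peptidome precursor genes to external gene-level measurements
# (expression/abundance rankings and protein turnover).

#' Bin peptidome genes by abundance rank
#'
#' Genes of an abundance table are ranked by descending value (stable
#' ties: equal values keep their input order, so binning is
#' reproducible); bin i covers ranks (i-1)*binSize+1 .. i*binSize. Each
#' queried gene is counted in its bin, or in \code{overflow} when it is
#' absent from the table or ranks below the last bin. Because only ranks
#' enter, the result is invariant under any strictly increasing
#' transform of the abundance values.
#'
#' @param values named numeric vector (gene -> abundance), e.g. from
#'   [readGeneValueTable()].
#' @param hits character vector of peptidome genes; duplicates are
#'   collapsed with a warning.
#' @param binSize genes per bin (e.g. 500 for a 5000-gene top list).
#' @param nBins number of bins.
#' @param uppercase upper-case both sides before matching.
#' @return list with \code{bins} (data.frame: bin, rank_lo, rank_hi,
#'   hits), \code{overflow}, and \code{n_hits}.
#' @export
rankBin <- function(values, hits, binSize, nBins, uppercase = TRUE) {
  stopifnot(binSize >= 1, nBins >= 1)
  if (uppercase) {
    names(values) <- toupper(names(values))
    hits <- toupper(hits)
  }
  if (anyDuplicated(hits)) {
    warning("duplicate hit genes collapsed")
    hits <- unique(hits)
  }
  ord <- order(-values)                      # radix: stable for ties
  rank <- setNames(seq_along(values), names(values)[ord])
  r <- rank[hits]                            # NA when absent
  lim <- binSize * nBins
  bin <- ceiling(r / binSize)
  inBin <- !is.na(r) & r <= lim
  counts <- tabulate(bin[inBin], nbins = nBins)
  bins <- data.frame(bin = seq_len(nBins),
                     rank_lo = (seq_len(nBins) - 1L) * binSize + 1L,
                     rank_hi = seq_len(nBins) * binSize,
                     hits = counts)
  list(bins = bins, overflow = sum(!inBin), n_hits = length(hits))
}

.halfLifeOne <- function(h, cap) {
  list(n = length(h),
       median_h = median(h),
       frac_le_3h = mean(h <= 3),
       frac_ge_cap = mean(h >= cap),
       percentile_curve = data.frame(percentile = 1:100,
                                     half_life = as.numeric(quantile(h, probs = (1:100) / 100))))
}

#' Half-life distribution of a gene subset vs the full table
#'
#' Half-life measurements are conventionally capped (100 h by default);
#' values above the cap are clamped on entry. Reports the median, the
#' fraction of short-lived proteins (<= 3 h), the fraction at the cap
#' (>= cap), and a percentile curve at 1% steps, for the queried subset
#' and for the whole table.
#'
#' @param values named numeric vector (gene -> half-life in hours).
#' @param subset optional character vector of genes; genes missing from
#'   the table are excluded and counted.
#' @param cap upper cap in hours (default 100).
#' @param uppercase upper-case gene ids before matching.
#' @return list with \code{subset} and \code{full} summaries (each as
#'   returned fields n/median_h/frac_le_3h/frac_ge_cap/percentile_curve)
#'   plus \code{n_found}/\code{n_missing} for the subset.
#' @export
halfLifeStats <- function(values, subset = NULL, cap = 100, uppercase = TRUE) {
  if (any(values <= 0)) stop("half-lives must be positive")
  if (uppercase) names(values) <- toupper(names(values))
  values <- pmin(values, cap)
  out <- list(full = .halfLifeOne(values, cap))
  if (!is.null(subset)) {
    if (uppercase) subset <- toupper(subset)
    found <- intersect(unique(subset), names(values))
    out$subset <- if (length(found)) .halfLifeOne(values[found], cap) else NULL
    out$n_found <- length(found)
    out$n_missing <- length(unique(subset)) - length(found)
  }
  out
}

#' Protein-length summary and rank curve
#'
#' @param x a \linkS4class{Proteome} or a numeric vector of lengths.
#' @return list with \code{mean_length}, \code{median_length} and a
#'   \code{curve} data.frame (rank, length) sorted ascending.
#' @export
lengthStats <- function(x) {
  len <- if (is(x, "Proteome")) unname(proteinLengths(x)) else as.numeric(x)
  if (!length(len)) stop("no proteins supplied")
  list(mean_length = mean(len),
       median_length = median(len),
       curve = data.frame(rank = seq_along(len), length = sort(len)))
}

#' Smallest protein set covering more than a fraction of the peptides
#'
#' How concentrated is the peptidome? Returns the smallest m such that
#' the m proteins with the most peptides account for strictly more than
#' \code{threshold} of all peptides (ties broken by descending count,
#' then lexicographic protein id). With \code{threshold = 1} this is the
#' number of proteins contributing at least one peptide.
#'
#' @param counts named integer vector (protein or gene -> number of
#'   peptides).
#' @param threshold fraction in (0, 1].
#' @return integer m.
#' @examples
#' minProteinsCovering(c(A = 3, B = 1), 0.5)  # 1
#' @export
minProteinsCovering <- function(counts, threshold = 0.5) {
  if (!length(counts)) stop("no peptide counts supplied")
  stopifnot(threshold > 0, threshold <= 1)
  counts <- counts[counts > 0]
  ord <- order(-counts, names(counts))
  cum <- cumsum(counts[ord])
  total <- sum(counts)
  if (threshold == 1) return(length(counts))
  m <- which(cum > threshold * total)[1]
  as.integer(m)
}
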
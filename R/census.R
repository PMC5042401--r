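# Descriptive peptidome statistics. Percentages are reported both as
# exact fractions and as display-rounded percents (composition to one
# decimal, terminal-location tallies to the nearest integer, following
# the conventions of published peptidome tables).

.peptideSeqs <- function(peptides, dedupe = TRUE) {
  s <- if (is.data.frame(peptides)) as.character(peptides$sequence) else as.character(peptides)
  if (dedupe) s <- unique(s)
  s
}

#' Amino-acid composition of a peptide set
#'
#' Counts every residue of every peptide. By default peptides observed
#' with multiple modification states of the same sequence are counted
#' once (\code{dedupe = TRUE}); set \code{dedupe = FALSE} to weight by
#' detections.
#'
#' @param peptides character vector or peptide table.
#' @param dedupe collapse to unique bare sequences first (default TRUE).
#' @return data.frame (one row per standard residue) with \code{count},
#'   \code{fraction} (exact, sums to 1) and \code{percent} (1 decimal);
#'   total residue count in attribute \code{"total"}.
#' @examples
#' aaComposition(c("ACDE"))
#' @export
aaComposition <- function(peptides, dedupe = TRUE) {
  s <- .peptideSeqs(peptides, dedupe)
  if (!length(s)) stop("no peptides supplied")
  .checkStandardResidues(s, "peptide sequence")
  counts <- alphabetFrequency(AAStringSet(s))
  counts <- colSums(counts[, AA_STANDARD, drop = FALSE])
  total <- sum(counts)
  out <- data.frame(residue = AA_STANDARD,
                    count = as.integer(counts),
                    fraction = as.numeric(counts / total),
                    percent = round(100 * counts / total, 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Frequencies of the peptide N-terminal residue
#'
#' Same layout as [aaComposition()] but counting only the first residue
#' of each peptide (denominator = number of peptides).
#'
#' @inheritParams aaComposition
#' @export
ntermResidueFreq <- function(peptides, dedupe = TRUE) {
  s <- .peptideSeqs(peptides, dedupe)
  if (!length(s)) stop("no peptides supplied")
  first <- substr(s, 1L, 1L)
  counts <- table(factor(first, levels = AA_STANDARD))
  total <- length(s)
  out <- data.frame(residue = AA_STANDARD,
                    count = as.integer(counts),
                    fraction = as.numeric(counts / total),
                    percent = round(100 * as.numeric(counts) / total, 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Fraction of N-terminally acetylated peptides
#'
#' @param peptides peptide table with an \code{n_acetyl} column (or a
#'   logical vector).
#' @param dedupe collapse to unique (sequence, acetyl) records first.
#' @return proportion in [0, 1]; 0 for an empty set.
#' @export
acetylFraction <- function(peptides, dedupe = TRUE) {
  if (is.data.frame(peptides)) {
    tbl <- peptides[, c("sequence", "n_acetyl")]
    if (dedupe) tbl <- unique(tbl)
    ac <- as.logical(tbl$n_acetyl)
  } else ac <- as.logical(peptides)
  if (!length(ac)) return(0)
  mean(ac)
}

#' Mass-distribution summary of a peptide set
#'
#' @param masses numeric vector of peptide masses (Da).
#' @param window numeric length-2, the mass window of interest
#'   (default 900-3000 Da).
#' @return list with \code{mean_mass}, \code{median_mass},
#'   \code{fraction_in_window} (inclusive bounds) and \code{window}.
#' @examples
#' sizeStats(c(1000, 2000, 3000))
#' @export
sizeStats <- function(masses, window = c(900, 3000)) {
  masses <- as.numeric(masses)
  if (!length(masses) || any(is.na(masses))) stop("masses must be non-empty and finite")
  list(mean_mass = mean(masses),
       median_mass = median(masses),
       fraction_in_window = mean(masses >= window[1] & masses <= window[2]),
       window = window)
}

#' Tally peptide positions within their precursor proteins
#'
#' Counts one terminal class per peptide. Individual classes are reported
#' along with the merged "N-term" super-category (initiator-Met present,
#' Met removed, or mature-protein N-terminus), which is how terminal
#' location is conventionally summarized.
#'
#' @param classes factor from [classifyTerminal()], one entry per
#'   peptide (use the canonical match of each peptide).
#' @return list with \code{by_class} (count/fraction/percent per class),
#'   \code{merged} (N-term / C-term / internal), and \code{denominator}.
#' @export
terminalTally <- function(classes) {
  classes <- factor(as.character(classes), levels = TERMINAL_CLASSES)
  n <- length(classes)
  counts <- table(classes)
  by_class <- data.frame(class = names(counts),
                         count = as.integer(counts),
                         fraction = if (n) as.numeric(counts / n) else rep(0, length(counts)),
                         stringsAsFactors = FALSE)
  by_class$percent <- round(100 * by_class$fraction)
  ntermN <- sum(counts[c("N_TERMINAL_WITH_MET", "N_TERMINAL_MET_REMOVED",
                         "MATURE_N_TERMINAL")])
  merged <- data.frame(
    class = c("N-term", "C-term", "internal"),
    count = c(ntermN, counts[["C_TERMINAL"]], counts[["INTERNAL"]]),
    stringsAsFactors = FALSE)
  merged$fraction <- if (n) merged$count / n else 0
  merged$percent <- round(100 * merged$fraction)
  list(by_class = by_class, merged = merged, denominator = n)
}

#' Tally cleavage-site P1 categories
#'
#' Two complementary denominators are reported, since published
#' cleavage-site preferences mix them: \code{per_site} is the fraction
#' of all cleavage sites (N-side and C-side pooled) whose P1 residue
#' falls in each category, and \code{per_peptide} is the fraction of
#' peptides having at least one site in the category.
#'
#' @param sites data.frame from [cleavageSites()].
#' @param nPeptides denominator for the per-peptide table; defaults to
#'   the number of distinct peptides appearing in \code{sites}. Supply
#'   the full peptide count explicitly when some peptides (whole-protein
#'   matches) contribute no sites.
#' @return list with \code{per_site}, \code{per_peptide} data.frames and
#'   the two denominators.
#' @export
cleavageTally <- function(sites, nPeptides = NULL) {
  if (is.null(nPeptides))
    nPeptides <- length(unique(sites$sequence))
  nSites <- nrow(sites)
  cat_levels <- P1_CATEGORIES
  siteCounts <- table(factor(sites$p1_category, levels = cat_levels))
  per_site <- data.frame(category = cat_levels,
                         count = as.integer(siteCounts),
                         fraction = if (nSites) as.numeric(siteCounts / nSites) else rep(0, 5),
                         stringsAsFactors = FALSE)
  per_site$percent <- round(100 * per_site$fraction, 1)
  pepCounts <- vapply(cat_levels, function(cc)
    length(unique(sites$sequence[sites$p1_category == cc])), integer(1))
  per_peptide <- data.frame(category = cat_levels,
                            count = pepCounts,
                            fraction = if (nPeptides) pepCounts / nPeptides else rep(0, 5),
                            stringsAsFactors = FALSE)
  per_peptide$percent <- round(100 * per_peptide$fraction, 1)
  list(per_site = per_site, per_peptide = per_peptide,
       n_sites = nSites, n_peptides = nPeptides)
}

#' Tally precursor proteins by annotation category
#'
#' Counts each protein once (regardless of how many peptides it
#' produced) by its annotated major intracellular location or primary
#' function; unannotated proteins fall into an "unknown" bucket.
#'
#' @param proteome a \linkS4class{Proteome}.
#' @param field \code{"location"} or \code{"function"}.
#' @return data.frame with \code{category}, \code{count},
#'   \code{fraction}, \code{percent}; denominator in attribute
#'   \code{"denominator"}.
#' @export
tallyByCategory <- function(proteome, field = c("location", "function")) {
  field <- match.arg(field)
  v <- if (field == "location") proteinMeta(proteome)$location else proteinMeta(proteome)$func
  v[is.na(v) | v == ""] <- "unknown"
  counts <- sort(table(v), decreasing = TRUE)
  n <- length(v)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    fraction = as.numeric(counts / n),
                    percent = round(100 * as.numeric(counts) / n),
                    stringsAsFactors = FALSE)
  attr(out, "denominator") <- n
  out
}
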
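# Packaged reference tables and batch summaries.

#' Background amino-acid composition of yeast proteins
#'
#' Reference composition (percent, with SD) of intracellular and nuclear
#' yeast proteins, from the compositional survey of Cedano et al. (1997,
#' J Mol Biol 266:594-600). Used as the comparison background for
#' peptidome composition tables and as the default residue frequencies
#' of the simulator.
#'
#' @return data.frame with columns \code{residue},
#'   \code{intracellular_pct}, \code{intracellular_sd},
#'   \code{nuclear_pct}, \code{nuclear_sd}.
#' @export
backgroundComposition <- function() {
  f <- system.file("extdata", "background_aa_composition.tsv",
                   package = "peptidomics", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}

#' Published proteasome-inhibitor peptide comparison (yeast)
#'
#' A published quantitative peptidomics summary of the 25 yeast peptides
#' detected in three or more LC-MS runs: pooled control mean/SEM/n and,
#' for four inhibitor contrasts (bortezomib in pdr5-delta, bortezomib in
#' snq2-delta, epoxomicin in snq2-delta, bortezomib in wild type), the
#' treated mean, SEM and significance mark (\code{NS}, \code{*} p<0.05,
#' \code{**} p<0.01, \code{***} p<0.001 by Student's t-test; \code{ND} =
#' not detected). Shipped as a worked real-data example for
#' [significanceTally()] and the rank/fold summaries.
#'
#' @return data.frame, one row per peptide.
#' @export
inhibitorPeptideTable <- function() {
  f <- system.file("extdata", "yeast_inhibitor_peptides.tsv",
                   package = "peptidomics", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Tally significant changes in a differential peptide table
#'
#' Counts, for one contrast of a table shaped like
#' [inhibitorPeptideTable()], the peptides detected, those significant
#' at any tier, and the direction of the significant changes (up =
#' treated mean above the control mean of 1).
#'
#' @param tbl data.frame from [inhibitorPeptideTable()] (or same
#'   layout).
#' @param contrast column prefix, e.g. \code{"pdr5_bortezomib"}.
#' @return list with \code{n_peptides}, \code{n_detected},
#'   \code{n_significant}, \code{n_up}, \code{n_down}.
#' @examples
#' significanceTally(inhibitorPeptideTable(), "pdr5_bortezomib")
#' @export
significanceTally <- function(tbl, contrast) {
  avg <- tbl[[paste0(contrast, "_avg")]]
  sig <- tbl[[paste0(contrast, "_sig")]]
  if (is.null(avg) || is.null(sig))
    stop("no columns for contrast ", contrast)
  detected <- !is.na(sig) & sig != "ND"
  isSig <- detected & sig %in% c("*", "**", "***")
  list(n_peptides = nrow(tbl),
       n_detected = sum(detected),
       n_significant = sum(isSig),
       n_up = sum(isSig & avg > 1),
       n_down = sum(isSig & avg < 1))
}

# terminal classification from flank markers (and start, when present),
# for peptide tables whose proteome is not at hand
.flankTerminalClass <- function(tbl) {
  cls <- rep("INTERNAL", nrow(tbl))
  cls[!is.na(tbl$downstream) & tbl$downstream == TERMINUS_MARK] <- "C_TERMINAL"
  if ("start" %in% names(tbl)) {
    metRemoved <- !is.na(tbl$start) & tbl$start == 2L &
      !is.na(tbl$upstream) & tbl$upstream == "M"
    cls[metRemoved] <- "N_TERMINAL_MET_REMOVED"
  }
  cls[!is.na(tbl$upstream) & tbl$upstream == TERMINUS_MARK] <- "N_TERMINAL_WITH_MET"
  factor(cls, levels = TERMINAL_CLASSES)
}

#' Summary statistics of an identified-peptide table
#'
#' One-pass summary of the peptidome-characterization statistics for a
#' peptide table (with flanking-residue columns) and its companion
#' protein table: amino-acid composition, N-terminal residue
#' frequencies, acetylation fraction, mass distribution, terminal
#' location (from the flank markers and start coordinates), per-peptide
#' basic/acidic/hydrophobic P1 fractions, protein-length statistics, and
#' the minimum protein set covering more than half the peptides.
#'
#' @param peptides peptide table (data.frame or TSV path): columns
#'   \code{sequence}, \code{n_acetyl}, \code{gene}, \code{upstream},
#'   \code{downstream}, \code{mass}, optionally \code{start}.
#' @param proteins optional protein table (data.frame or TSV path) with
#'   columns \code{gene} and \code{length}.
#' @return list of summaries; see Details in the individual census
#'   functions.
#' @export
supplementaryTableSummary <- function(peptides, proteins = NULL) {
  if (is.character(peptides)) peptides <- readPeptideTable(peptides)
  pep <- unique(peptides[, intersect(c("sequence", "n_acetyl", "gene", "start",
                                       "upstream", "downstream", "mass"),
                                     names(peptides))])
  comp <- aaComposition(pep$sequence, dedupe = TRUE)
  nterm <- ntermResidueFreq(pep$sequence, dedupe = TRUE)
  cls <- .flankTerminalClass(pep)
  tt <- terminalTally(cls)
  # per-peptide P1 category fractions, pooling N-side and C-side sites
  n <- nrow(pep)
  catOf <- function(res) as.character(classifyP1(res))
  hasCat <- function(cat) {
    vapply(seq_len(n), function(i) {
      cats <- character(0)
      if (!is.na(pep$upstream[i]) && pep$upstream[i] != TERMINUS_MARK)
        cats <- c(cats, catOf(pep$upstream[i]))
      if (!is.na(pep$downstream[i]) && pep$downstream[i] != TERMINUS_MARK)
        cats <- c(cats, catOf(substr(pep$sequence[i], nchar(pep$sequence[i]),
                                     nchar(pep$sequence[i]))))
      cat %in% cats
    }, logical(1))
  }
  p1 <- vapply(P1_CATEGORIES, function(cc) mean(hasCat(cc)), numeric(1))
  out <- list(
    n_peptides = n,
    composition = comp,
    nterm_freq = nterm,
    acetyl_fraction = acetylFraction(pep),
    size = if ("mass" %in% names(pep)) sizeStats(pep$mass) else NULL,
    terminal = tt,
    p1_per_peptide = p1,
    min_cover_half = minProteinsCovering(table(pep$gene), 0.5),
    n_genes = length(unique(pep$gene))
  )
  if (!is.null(proteins)) {
    if (is.character(proteins)) proteins <- read.delim(proteins, stringsAsFactors = FALSE)
    out$protein_lengths <- lengthStats(proteins$length)
    out$n_proteins <- nrow(proteins)
  }
  out
}
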
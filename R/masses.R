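# Monoisotopic mass computation. Residue masses are derived from atomic
# monoisotopic masses (CODATA/AME) and elemental residue formulas rather
# than hard-coded per-residue constants, so modification deltas and label
# masses stay consistent with the same atom table.

.ATOMIC_MASS <- c(
  H = 1.00782503207,
  D = 2.01410177785,  # deuterium, for isotopic label deltas
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# residue (= amino acid minus water) elemental composition, C/H/N/O/S
.RESIDUE_FORMULA <- rbind(
  A = c(3, 5, 1, 1, 0),
  R = c(6, 12, 4, 1, 0),
  N = c(4, 6, 2, 2, 0),
  D = c(4, 5, 1, 3, 0),
  C = c(3, 5, 1, 1, 1),
  E = c(5, 7, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0),
  G = c(2, 3, 1, 1, 0),
  H = c(6, 7, 3, 1, 0),
  I = c(6, 11, 1, 1, 0),
  L = c(6, 11, 1, 1, 0),
  K = c(6, 12, 2, 1, 0),
  M = c(5, 9, 1, 1, 1),
  F = c(9, 9, 1, 1, 0),
  P = c(5, 7, 1, 1, 0),
  S = c(3, 5, 1, 2, 0),
  T = c(4, 7, 1, 2, 0),
  W = c(11, 10, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),
  V = c(5, 9, 1, 1, 0)
)
colnames(.RESIDUE_FORMULA) <- c("C", "H", "N", "O", "S")

.MASS_WATER <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
.MASS_ACETYL <- 2 * .ATOMIC_MASS[["C"]] + 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
.MASS_OXIDATION <- .ATOMIC_MASS[["O"]]

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of monoisotopic residue masses (Da) for
#'   the 20 standard amino acids, computed from atomic masses.
#' @examples
#' residueMasses()[["G"]]  # 57.02146
#' @export
residueMasses <- function() {
  m <- .RESIDUE_FORMULA %*% .ATOMIC_MASS[colnames(.RESIDUE_FORMULA)]
  setNames(as.numeric(m), rownames(.RESIDUE_FORMULA))[AA_STANDARD]
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus 42.01057 Da per N-terminal
#' acetyl group and 15.99491 Da per oxidized methionine. The mass of the
#' bare (unlabeled) peptide is returned: isotopic label tags are reported
#' separately by [tmabLabelMasses()], matching the convention of peptide
#' identification tables which list unlabeled masses.
#'
#' @param sequences character vector of peptide sequences (standard
#'   one-letter codes only; nonstandard codes are an error).
#' @param nAcetyl logical (or 0/1) vector: N-terminally acetylated?
#' @param nOxMet integer vector: number of oxidized methionines.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopicMass("G")                   # 75.03203
#' monoisotopicMass("AG")                  # 146.06914
#' monoisotopicMass("G", nAcetyl = TRUE)   # 117.04260
#' @export
monoisotopicMass <- function(sequences, nAcetyl = FALSE, nOxMet = 0L) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  sequences <- as.character(sequences)
  if (any(is.na(sequences) | nchar(sequences) == 0L))
    stop("empty peptide sequence")
  .checkStandardResidues(sequences, "peptide sequence")
  nAcetyl <- rep_len(as.logical(nAcetyl), length(sequences))
  nOxMet <- rep_len(as.integer(nOxMet), length(sequences))
  rm <- residueMasses()
  vapply(seq_along(sequences), function(i) {
    res <- strsplit(sequences[i], "")[[1]]
    sum(rm[res]) + .MASS_WATER +
      (if (nAcetyl[i]) .MASS_ACETYL else 0) +
      nOxMet[i] * .MASS_OXIDATION
  }, numeric(1))
}

# mass added per peptide by a peptide-table row (acetyl + Met oxidation)
.tableModMass <- function(tbl) {
  nox <- vapply(.parseOxMet(tbl$ox_met), length, integer(1))
  as.logical(tbl$n_acetyl) * .MASS_ACETYL + nox * .MASS_OXIDATION
}

#' TMAB isotopic label mass additions
#'
#' Mass added to a free amine by acylation with a
#' 4-trimethylammoniumbutyryl (TMAB) tag: the D0 tag adds the
#' trimethylammoniumbutyryl group (net of the amine hydrogen it
#' replaces), and the D3/D6/D9 tags add 3/6/9 deuterium-for-hydrogen
#' substitutions on top. Provided for users validating raw peak masses;
#' [monoisotopicMass()] deliberately excludes label mass.
#'
#' @return Named numeric vector (Da) for D0, D3, D6, D9.
#' @examples
#' tmabLabelMasses()  # D0 approximately 128.108 Da
#' @export
tmabLabelMasses <- function() {
  a <- .ATOMIC_MASS
  # acyl group -CO-CH2CH2CH2-N+(CH3)3 is C7H15NO; acylation replaces one
  # amine hydrogen, so the net addition is C7H14NO (charge ignored)
  d0 <- 7 * a[["C"]] + 14 * a[["H"]] + a[["N"]] + a[["O"]]
  dh <- a[["D"]] - a[["H"]]
  c(D0 = d0, D3 = d0 + 3 * dh, D6 = d0 + 6 * dh, D9 = d0 + 9 * dh)
}
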
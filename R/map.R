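# Peptide-to-proteome mapping and positional classification.
#
# Endogenous peptides are not digested with a site-specific protease, so
# a peptide can in principle occur anywhere in any protein (and in more
# than one paralog, e.g. identical stretches of TDH1/TDH3). Mapping is
# exact substring search; I and L are distinct characters (identities
# come from MS/MS search engines that assigned one of them).

TERMINAL_CLASSES <- c("N_TERMINAL_WITH_MET", "N_TERMINAL_MET_REMOVED",
                      "MATURE_N_TERMINAL", "C_TERMINAL", "INTERNAL")

P1_CATEGORIES <- c("ACIDIC", "BASIC", "HYDROPHOBIC", "PRO", "OTHER")

#' Map peptides onto a proteome
#'
#' Finds every exact occurrence of each peptide in the proteome and fills
#' in 1-based inclusive coordinates and flanking residues (\code{"-"}
#' when the peptide touches a protein terminus). Peptides matching
#' several proteins get one row per occurrence; when the input annotates
#' a gene, the occurrence in that gene is marked \code{canonical} (used
#' by the census functions, which count each peptide once). Peptides with
#' no occurrence anywhere are returned with zero rows and reported via
#' the \code{"unmapped"} attribute; a gene annotation that conflicts with
#' every occurrence gives a warning, not an error.
#'
#' @param peptides character vector of peptide sequences, or a peptide
#'   table (data.frame with \code{sequence} and optionally \code{gene}).
#' @param proteome a \linkS4class{Proteome}.
#' @return data.frame with columns \code{sequence}, \code{protein_id},
#'   \code{gene}, \code{start}, \code{end}, \code{upstream},
#'   \code{downstream}, \code{canonical}; occurrences ordered by
#'   (peptide, protein id, start).
#' @examples
#' prot <- Proteome(c(P1 = "AASTLPEIYEKG"), gene = "ADH1")
#' mapPeptides("STLPEIYEK", prot)
#' @export
mapPeptides <- function(peptides, proteome) {
  if (length(proteome) == 0L) stop("proteome is empty")
  annGene <- NULL
  if (is.data.frame(peptides)) {
    annGene <- if ("gene" %in% names(peptides)) as.character(peptides$gene)
    peptides <- as.character(peptides$sequence)
  }
  if (!length(peptides)) stop("no peptides supplied")
  .checkStandardResidues(peptides, "peptide sequence")
  seqs <- proteome@sequences
  lens <- proteinLengths(proteome)
  genes <- proteinGenes(proteome)
  pseq <- proteinSequences(proteome)
  ids <- proteinIds(proteome)

  uniq <- unique(peptides)
  hitList <- lapply(uniq, function(p) {
    m <- vmatchPattern(p, seqs)
    starts <- lapply(m, IRanges::start)
    n <- lengths(starts)
    if (!sum(n)) return(NULL)
    data.frame(
      sequence = p,
      protein_id = rep(ids, n),
      start = unlist(starts, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  })
  names(hitList) <- uniq
  unmapped <- uniq[vapply(hitList, is.null, logical(1))]

  rows <- lapply(seq_along(peptides), function(i) {
    h <- hitList[[peptides[i]]]
    if (is.null(h)) return(NULL)
    h <- h[order(h$protein_id, h$start), , drop = FALSE]
    k <- nchar(h$sequence[1])
    h$end <- h$start + k - 1L
    h$gene <- unname(genes[h$protein_id])
    L <- lens[h$protein_id]
    h$upstream <- ifelse(h$start == 1L, TERMINUS_MARK,
                         substr(pseq[h$protein_id], h$start - 1L, h$start - 1L))
    h$downstream <- ifelse(h$end == L, TERMINUS_MARK,
                           substr(pseq[h$protein_id], h$end + 1L, h$end + 1L))
    h$canonical <- FALSE
    if (!is.null(annGene) && !is.na(annGene[i]) && annGene[i] != "") {
      pick <- which(h$gene == annGene[i])
      if (!length(pick)) {
        warning("peptide ", h$sequence[1], ": annotated gene ", annGene[i],
                " not among matched genes (", paste(unique(h$gene), collapse = ", "),
                "); first occurrence marked canonical")
        pick <- 1L
      }
    } else pick <- 1L
    h$canonical[pick[1]] <- TRUE
    h[, c("sequence", "protein_id", "gene", "start", "end",
          "upstream", "downstream", "canonical")]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(sequence = character(), protein_id = character(),
                      gene = character(), start = integer(), end = integer(),
                      upstream = character(), downstream = character(),
                      canonical = logical(), stringsAsFactors = FALSE)
  attr(out, "unmapped") <- unmapped
  out
}

.matchProteinCheck <- function(matches, proteome) {
  bad <- setdiff(unique(matches$protein_id), proteinIds(proteome))
  if (length(bad))
    stop("matches refer to protein id(s) absent from the proteome: ",
         paste(bad, collapse = ", "))
  pseq <- proteinSequences(proteome)
  got <- substr(pseq[matches$protein_id], matches$start, matches$end)
  if (any(got != matches$sequence))
    stop("match coordinates inconsistent with protein sequences (rows ",
         paste(head(which(got != matches$sequence), 5), collapse = ", "), ")")
  invisible(TRUE)
}

#' Classify the position of matched peptides within their proteins
#'
#' A peptide starting at residue 1 is N-terminal (with the initiator
#' Met); one starting at residue 2 of a Met-initiated protein is
#' N-terminal with the Met removed (initiator-Met excision); one starting
#' at an annotated mature-protein N-terminus is a mature-N-terminal
#' fragment; one containing the last residue is C-terminal; everything
#' else is internal. A peptide that is both N- and C-terminal (e.g. a
#' whole-protein match) is classified N-terminal: the categories are
#' exclusive and the N rules take precedence.
#'
#' @param matches data.frame from [mapPeptides()].
#' @param proteome the \linkS4class{Proteome} the matches refer to.
#' @return factor with levels
#'   \code{N_TERMINAL_WITH_MET, N_TERMINAL_MET_REMOVED,
#'   MATURE_N_TERMINAL, C_TERMINAL, INTERNAL}, one per match row.
#' @export
classifyTerminal <- function(matches, proteome) {
  if (!nrow(matches)) return(factor(character(), levels = TERMINAL_CLASSES))
  .matchProteinCheck(matches, proteome)
  lens <- proteinLengths(proteome)[matches$protein_id]
  first <- substr(proteinSequences(proteome)[matches$protein_id], 1L, 1L)
  ms <- proteinMeta(proteome)$mature_start[match(matches$protein_id, proteinIds(proteome))]
  cls <- rep("INTERNAL", nrow(matches))
  cls[matches$end == lens] <- "C_TERMINAL"
  mature <- !is.na(ms) & matches$start == ms
  cls[mature] <- "MATURE_N_TERMINAL"
  cls[matches$start == 2L & first == "M"] <- "N_TERMINAL_MET_REMOVED"
  cls[matches$start == 1L] <- "N_TERMINAL_WITH_MET"
  factor(cls, levels = TERMINAL_CLASSES)
}

#' Extract cleavage sites of matched peptides
#'
#' Each matched peptide implies up to two scissile bonds: an N-side site
#' (P1 = upstream flanking residue, P1' = first peptide residue) when the
#' peptide does not start at the protein N-terminus, and a C-side site
#' (P1 = last peptide residue, P1' = downstream flanking residue) when it
#' does not end at the C-terminus. Protein-terminal boundaries are not
#' cleavage sites and yield nothing.
#'
#' @param matches data.frame from [mapPeptides()].
#' @param proteome the \linkS4class{Proteome} the matches refer to.
#' @return data.frame with columns \code{sequence}, \code{protein_id},
#'   \code{side} (\code{N_SIDE}/\code{C_SIDE}), \code{p1},
#'   \code{p1_prime}, \code{p1_category}.
#' @export
cleavageSites <- function(matches, proteome) {
  if (!nrow(matches))
    return(data.frame(sequence = character(), protein_id = character(),
                      side = character(), p1 = character(),
                      p1_prime = character(), p1_category = character(),
                      stringsAsFactors = FALSE))
  .matchProteinCheck(matches, proteome)
  k <- nchar(matches$sequence)
  nSide <- matches$upstream != TERMINUS_MARK
  cSide <- matches$downstream != TERMINUS_MARK
  out <- rbind(
    data.frame(sequence = matches$sequence[nSide],
               protein_id = matches$protein_id[nSide],
               side = rep("N_SIDE", sum(nSide)),
               p1 = matches$upstream[nSide],
               p1_prime = substr(matches$sequence[nSide], 1L, 1L),
               stringsAsFactors = FALSE),
    data.frame(sequence = matches$sequence[cSide],
               protein_id = matches$protein_id[cSide],
               side = rep("C_SIDE", sum(cSide)),
               p1 = substr(matches$sequence[cSide], k[cSide], k[cSide]),
               p1_prime = matches$downstream[cSide],
               stringsAsFactors = FALSE)
  )
  ord <- order(match(paste(out$sequence, out$protein_id),
                     paste(matches$sequence, matches$protein_id)),
               out$side != "N_SIDE")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$p1_category <- as.character(classifyP1(out$p1))
  out
}

#' Classify a P1 residue
#'
#' Category of the residue N-terminal to a scissile bond, following the
#' substrate preferences of the three catalytic proteasome subunits:
#' acidic (D, E), basic (K, R), hydrophobic (L, M, V, A, F, Y, W),
#' proline, or other.
#'
#' @param residues character vector of single standard residue codes.
#' @return factor with levels
#'   \code{ACIDIC, BASIC, HYDROPHOBIC, PRO, OTHER}.
#' @examples
#' classifyP1(c("K", "W", "G"))
#' @export
classifyP1 <- function(residues) {
  residues <- as.character(residues)
  if (any(is.na(residues) | !residues %in% AA_STANDARD))
    stop("P1 classification needs single standard residue codes; got: ",
         paste(unique(residues[!residues %in% AA_STANDARD]), collapse = ", "))
  cls <- rep("OTHER", length(residues))
  cls[residues %in% c("D", "E")] <- "ACIDIC"
  cls[residues %in% c("K", "R")] <- "BASIC"
  cls[residues %in% c("L", "M", "V", "A", "F", "Y", "W")] <- "HYDROPHOBIC"
  cls[residues == "P"] <- "PRO"
  factor(cls, levels = P1_CATEGORIES)
}

#' Expected fraction of terminal peptides under uniform sampling
#'
#' For a protein of length L and peptide length k there are
#' W = L - k + 1 possible peptide windows, of which at most two touch a
#' terminus. If peptides arose uniformly at random along the protein, the
#' probability of a terminal peptide would be min(2, W)/W -- below 1% for
#' typical proteins (L 300-400) and peptides (k about 15). Observed
#' terminal fractions far above this are evidence of positional
#' enrichment.
#'
#' @param L protein length(s), residues.
#' @param k peptide length(s), residues; must satisfy 1 <= k <= L.
#' @return numeric fraction in (0, 1].
#' @examples
#' expectedTerminalFraction(350, 15)  # about 0.00595
#' @export
expectedTerminalFraction <- function(L, k) {
  L <- as.numeric(L); k <- as.numeric(k)
  if (any(k < 1) || any(k > L))
    stop("need 1 <= k <= L")
  W <- L - k + 1
  pmin(2, W) / W
}
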
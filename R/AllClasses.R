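#' Proteome: a set of protein sequences with annotations
#'
#' Container for a proteome used as the search space for peptide mapping.
#' Wraps a \link[Biostrings]{AAStringSet} plus a per-protein annotation
#' \link[S4Vectors]{DataFrame} with columns \code{gene}, \code{location},
#' \code{func}, \code{mature_start} (1-based index of the mature-protein
#' N-terminus, NA when the protein has no cleaved precursor sequence) and
#' optionally \code{abundance}.
#'
#' All coordinates in this package are 1-based and inclusive.
#'
#' @slot sequences AAStringSet, named by protein accession.
#' @slot meta DataFrame with one row per protein.
#'
#' @seealso [readProteome()], [mapPeptides()]
#' @export
setClass("Proteome",
         slots = c(sequences = "AAStringSet", meta = "DataFrame"))

setValidity("Proteome", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all sequences must be named by a protein accession")
  if (anyDuplicated(ids))
    return("protein accessions must be unique")
  if (nrow(object@meta) != length(object@sequences))
    return("meta must have one row per sequence")
  need <- c("gene", "location", "func", "mature_start")
  if (!all(need %in% colnames(object@meta)))
    return(paste("meta must contain columns:", paste(need, collapse = ", ")))
  seqs <- as.character(object@sequences)
  if (any(nchar(seqs) == 0L))
    return("empty protein sequence")
  ok <- !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), seqs)
  if (!all(ok))
    return(paste("nonstandard residues in protein(s):",
                 paste(head(ids[!ok], 5), collapse = ", ")))
  ms <- object@meta$mature_start
  len <- nchar(seqs)
  bad <- !is.na(ms) & (ms < 2 | ms > len)
  if (any(bad))
    return("mature_start must lie in [2, protein length]")
  TRUE
})

#' Construct a Proteome
#'
#' @param sequences named character vector or AAStringSet of protein
#'   sequences (names are accessions).
#' @param gene gene symbol per protein (defaults to the accession).
#' @param location,func optional category annotations (e.g. the major
#'   intracellular location / primary function curated for each protein).
#' @param matureStart optional 1-based residue index of the mature-protein
#'   N-terminus (for proteins whose precursor sequence is removed).
#' @param abundance optional numeric abundance (copy number, FPKM, ...).
#' @return A \linkS4class{Proteome}.
#' @examples
#' p <- Proteome(c(P1 = "MAVKTTLPEIYEKG"), gene = "ADH1")
#' proteinLengths(p)
#' @export
Proteome <- function(sequences, gene = NULL, location = NULL, func = NULL,
                     matureStart = NULL, abundance = NULL) {
  if (!is(sequences, "AAStringSet")) {
    .checkStandardResidues(sequences, "protein sequence")
    sequences <- AAStringSet(sequences)
  }
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named by a protein accession")
  meta <- DataFrame(
    gene = if (is.null(gene)) ids else rep_len(as.character(gene), n),
    location = if (is.null(location)) rep(NA_character_, n) else rep_len(as.character(location), n),
    func = if (is.null(func)) rep(NA_character_, n) else rep_len(as.character(func), n),
    mature_start = if (is.null(matureStart)) rep(NA_integer_, n) else rep_len(as.integer(matureStart), n)
  )
  if (!is.null(abundance)) meta$abundance <- rep_len(as.numeric(abundance), n)
  rownames(meta) <- ids
  new("Proteome", sequences = sequences, meta = meta)
}

setMethod("show", "Proteome", function(object) {
  cat("Proteome with", length(object@sequences), "proteins\n")
  len <- Biostrings::width(object@sequences)
  cat("  length: mean", round(mean(len), 1), "| median", median(len),
      "| range", min(len), "-", max(len), "\n")
  ann <- colnames(object@meta)[!vapply(object@meta, function(x) all(is.na(x)), logical(1))]
  cat("  annotations:", paste(ann, collapse = ", "), "\n")
})

setMethod("length", "Proteome", function(x) length(x@sequences))

setMethod("[", "Proteome", function(x, i, j, ..., drop = TRUE) {
  new("Proteome", sequences = x@sequences[i], meta = x@meta[i, , drop = FALSE])
})

#' @describeIn Proteome protein accessions.
#' @param x,object a Proteome.
#' @export
proteinIds <- function(x) names(x@sequences)

#' @describeIn Proteome gene symbols, named by accession.
#' @export
proteinGenes <- function(x) setNames(x@meta$gene, proteinIds(x))

#' @describeIn Proteome protein lengths in residues, named by accession.
#' @export
proteinLengths <- function(x) setNames(Biostrings::width(x@sequences), proteinIds(x))

#' @describeIn Proteome sequences as a named character vector.
#' @export
proteinSequences <- function(x) setNames(as.character(x@sequences), proteinIds(x))

#' @describeIn Proteome the per-protein annotation DataFrame.
#' @export
proteinMeta <- function(x) x@meta


#' ChannelDesign: labeling scheme of one LC-MS run
#'
#' Describes which isotopic label channel carries which biological sample
#' in one multiplexed run: each channel is assigned a group (CONTROL or
#' TREATED) and a replicate identifier. A valid design has at least one
#' CONTROL channel; the canonical 4-plex design has two control and two
#' treated biological replicates.
#'
#' @slot runId run identifier.
#' @slot channels ordered channel (label) names, e.g. D0, D3, D6, D9.
#' @slot group named character, channel -> "CONTROL"/"TREATED".
#' @slot replicate named character, channel -> replicate id.
#' @export
setClass("ChannelDesign",
         slots = c(runId = "character", channels = "character",
                   group = "character", replicate = "character"))

setValidity("ChannelDesign", function(object) {
  if (length(object@runId) != 1L) return("runId must be a single string")
  if (anyDuplicated(object@channels)) return("channel names must be unique within a run")
  if (!setequal(names(object@group), object@channels) ||
      !setequal(names(object@replicate), object@channels))
    return("group and replicate must be named by the channels")
  if (!all(object@group %in% c("CONTROL", "TREATED")))
    return("group values must be CONTROL or TREATED")
  if (!any(object@group == "CONTROL"))
    return("a design needs at least one CONTROL channel")
  TRUE
})

#' Construct a ChannelDesign
#'
#' @param runId run identifier (string).
#' @param channels ordered channel names.
#' @param groups character vector ("CONTROL"/"TREATED"), one per channel.
#' @param replicates replicate ids, one per channel; defaults to
#'   group-wise numbering (C1, C2, T1, ...).
#' @return A \linkS4class{ChannelDesign}.
#' @examples
#' channelDesign("run1", c("D0", "D3", "D6", "D9"),
#'               c("CONTROL", "CONTROL", "TREATED", "TREATED"))
#' @export
channelDesign <- function(runId, channels, groups, replicates = NULL) {
  groups <- toupper(rep_len(groups, length(channels)))
  if (is.null(replicates)) {
    replicates <- character(length(channels))
    replicates[groups == "CONTROL"] <- paste0("C", seq_len(sum(groups == "CONTROL")))
    replicates[groups == "TREATED"] <- paste0("T", seq_len(sum(groups == "TREATED")))
  }
  new("ChannelDesign", runId = as.character(runId), channels = channels,
      group = setNames(groups, channels),
      replicate = setNames(as.character(replicates), channels))
}

setMethod("show", "ChannelDesign", function(object) {
  cat("ChannelDesign for run", object@runId, "\n")
  for (ch in object@channels)
    cat("  ", ch, ": ", object@group[[ch]], " (", object@replicate[[ch]], ")\n", sep = "")
})

#' @describeIn ChannelDesign all channel names, in order.
#' @param x a ChannelDesign.
#' @export
designChannels <- function(x) x@channels

#' @describeIn ChannelDesign channels assigned to the control group.
#' @export
controlChannels <- function(x) x@channels[x@group[x@channels] == "CONTROL"]

#' @describeIn ChannelDesign channels assigned to the treated group.
#' @export
treatedChannels <- function(x) x@channels[x@group[x@channels] == "TREATED"]

#' @describeIn ChannelDesign run identifier.
#' @export
designRunId <- function(x) x@runId


#' MultiAlignment: a gapped alignment of 2-3 sequences
#'
#' Rows are gapped strings of equal width; removing the gap characters
#' from any row reproduces the input sequence exactly.
#'
#' @slot rows named character vector of gapped sequences.
#' @slot score alignment score (NA for progressive alignments).
#' @export
setClass("MultiAlignment",
         slots = c(rows = "character", score = "numeric"))

setValidity("MultiAlignment", function(object) {
  if (length(object@rows) < 2L) return("an alignment needs at least 2 rows")
  if (is.null(names(object@rows))) return("rows must be named")
  if (length(unique(nchar(object@rows))) != 1L)
    return("all gapped rows must have equal width")
  TRUE
})

setMethod("show", "MultiAlignment", function(object) {
  cat("MultiAlignment:", length(object@rows), "rows x",
      nchar(object@rows[[1]]), "columns")
  if (!is.na(object@score)) cat(" | score", object@score)
  cat("\n")
  w <- max(nchar(names(object@rows)))
  for (i in seq_along(object@rows))
    cat(sprintf("  %-*s %s\n", w, names(object@rows)[i], object@rows[[i]]))
})

#' @describeIn MultiAlignment gapped rows as a named character vector.
#' @param x,object a MultiAlignment.
#' @export
alignmentRows <- function(x) x@rows

#' @describeIn MultiAlignment alignment score (NA if not applicable).
#' @export
alignmentScore <- function(x) x@score

#' @describeIn MultiAlignment ungapped input sequences, named.
#' @export
ungap <- function(x) setNames(gsub("-", "", x@rows, fixed = TRUE), names(x@rows))


#' SubstitutionScheme: scoring scheme for global alignment
#'
#' A symmetric substitution matrix plus affine gap penalties. A gap of
#' length g costs \code{gapOpen + g * gapExtend} (so a linear per-residue
#' gap cost of 1 is \code{gapOpen = 0, gapExtend = 1}).
#'
#' @slot matrix symmetric numeric substitution matrix.
#' @slot gapOpen,gapExtend non-negative penalties.
#' @export
setClass("SubstitutionScheme",
         slots = c(matrix = "matrix", gapOpen = "numeric", gapExtend = "numeric"))

setValidity("SubstitutionScheme", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("substitution matrix must have identical row and column names")
  if (!isTRUE(all.equal(m, t(m)))) return("substitution matrix must be symmetric")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties must be >= 0")
  TRUE
})

#' Construct a substitution scheme
#'
#' @param matrix either a symmetric numeric matrix, or the name
#'   \code{"BLOSUM62"} (loaded from Biostrings), or \code{"simple"} for a
#'   match/mismatch matrix over the 20 standard residues.
#' @param match,mismatch scores used when \code{matrix = "simple"}.
#' @param gapOpen,gapExtend affine gap penalties; a gap of length g costs
#'   \code{gapOpen + g * gapExtend}. Defaults (BLOSUM62, open 10,
#'   extend 0.5) follow common practice for protein global alignment.
#' @return A \linkS4class{SubstitutionScheme}.
#' @examples
#' substitutionScheme("simple", match = 1, mismatch = -1,
#'                    gapOpen = 0, gapExtend = 1)
#' @export
substitutionScheme <- function(matrix = "BLOSUM62", match = 1, mismatch = -1,
                               gapOpen = 10, gapExtend = 0.5) {
  if (is.character(matrix) && length(matrix) == 1L) {
    if (matrix == "BLOSUM62") {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[AA_STANDARD, AA_STANDARD]
      mode(m) <- "numeric"
    } else if (matrix == "simple") {
      m <- base::matrix(mismatch, 20, 20, dimnames = list(AA_STANDARD, AA_STANDARD))
      diag(m) <- match
    } else stop("unknown named matrix: ", matrix)
    matrix <- m
  }
  new("SubstitutionScheme", matrix = matrix,
      gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}
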
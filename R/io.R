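# File formats. All tables are plain TSV with a header row; FASTA headers
# carry optional "key=value" annotations after the accession. Coordinates
# are 1-based inclusive everywhere; "-" marks a protein terminus in flank
# columns; an empty intensity cell means "not detected".

#' Read a proteome from FASTA
#'
#' Headers are parsed as \code{accession key=value ...}; recognized keys
#' are \code{gene}, \code{loc}, \code{func}, \code{mature_start} and
#' \code{abundance}. Unannotated headers are fine.
#'
#' @param file path to a FASTA file.
#' @return A \linkS4class{Proteome}.
#' @export
readProteome <- function(file) {
  ss <- readAAStringSet(file)
  headers <- names(ss)
  parts <- strsplit(headers, "\\s+")
  ids <- vapply(parts, `[`, character(1), 1)
  getkv <- function(key) {
    vapply(parts, function(p) {
      hit <- grep(paste0("^", key, "="), p, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }, character(1))
  }
  names(ss) <- ids
  gene <- getkv("gene")
  gene[is.na(gene)] <- ids[is.na(gene)]
  ms <- suppressWarnings(as.integer(getkv("mature_start")))
  ab <- suppressWarnings(as.numeric(getkv("abundance")))
  Proteome(ss, gene = gene, location = getkv("loc"), func = getkv("func"),
           matureStart = ms,
           abundance = if (all(is.na(ab))) NULL else ab)
}

#' Write a Proteome to FASTA
#'
#' Inverse of [readProteome()]: annotations present in the metadata are
#' emitted as \code{key=value} pairs on the header line.
#'
#' @param x a Proteome.
#' @param file output path.
#' @export
writeProteome <- function(x, file) {
  m <- proteinMeta(x)
  hdr <- proteinIds(x)
  add <- function(hdr, key, v) {
    keep <- !is.na(v)
    hdr[keep] <- paste0(hdr[keep], " ", key, "=", v[keep])
    hdr
  }
  hdr <- add(hdr, "gene", m$gene)
  hdr <- add(hdr, "loc", m$location)
  hdr <- add(hdr, "func", m$func)
  hdr <- add(hdr, "mature_start", m$mature_start)
  if (!is.null(m$abundance)) hdr <- add(hdr, "abundance", signif(m$abundance, 8))
  ss <- x@sequences
  names(ss) <- hdr
  writeXStringSet(ss, file, width = 60)
  invisible(file)
}

.parseOxMet <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Read an identified-peptide table
#'
#' TSV with header; required columns \code{sequence}, \code{n_acetyl}
#' (0/1), \code{ox_met} (semicolon-joined 1-based indices of oxidized
#' methionines, may be empty), \code{gene}; optional \code{protein_id},
#' \code{start}, \code{end}, \code{upstream}, \code{downstream},
#' \code{mass}. Missing coordinates can be reconstructed with
#' [mapPeptides()]. \code{"-"} in a flank column denotes a protein
#' terminus.
#'
#' @param file path to TSV.
#' @return data.frame, validated (standard residues; every ox_met index
#'   points at an M).
#' @export
readPeptideTable <- function(file) {
  tbl <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  need <- c("sequence", "n_acetyl", "ox_met", "gene")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("peptide table ", file, " lacks column(s): ", paste(miss, collapse = ", "))
  tbl$ox_met[is.na(tbl$ox_met)] <- ""
  validatePeptideTable(tbl)
  tbl
}

#' Validate an identified-peptide table
#'
#' Checks the invariants of a peptide record: non-empty standard-residue
#' sequences and oxidized-Met indices that point at methionines.
#'
#' @param tbl data.frame as from [readPeptideTable()].
#' @return the table, invisibly; errors describe the offending rows.
#' @export
validatePeptideTable <- function(tbl) {
  if (any(is.na(tbl$sequence) | nchar(tbl$sequence) == 0L))
    stop("peptide table contains empty sequences")
  .checkStandardResidues(tbl$sequence, "peptide sequence")
  ox <- .parseOxMet(tbl$ox_met)
  for (i in seq_along(ox)) {
    if (!length(ox[[i]])) next
    res <- strsplit(tbl$sequence[i], "")[[1]]
    bad <- ox[[i]] < 1 | ox[[i]] > length(res) | res[pmin(pmax(ox[[i]], 1), length(res))] != "M"
    if (any(bad))
      stop("row ", i, " (", tbl$sequence[i], "): ox_met index ",
           paste(ox[[i]][bad], collapse = ";"), " does not point at an M")
  }
  invisible(tbl)
}

#' Write a peptide table
#' @param tbl data.frame of peptide records.
#' @param file output path.
#' @export
writePeptideTable <- function(tbl, file) {
  write.table(tbl, file, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' Read a per-channel intensity table
#'
#' TSV with columns \code{run_id}, \code{sequence}, \code{mod_signature},
#' \code{charge}, then one numeric column per label channel. An empty
#' cell means the peak was not detected in that channel.
#'
#' @param file path to TSV.
#' @param channels optional channel names to check for.
#' @return data.frame with NA for not-detected intensities.
#' @export
readIntensityTable <- function(file, channels = NULL) {
  tbl <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  need <- c("run_id", "sequence", "mod_signature", "charge")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("intensity table ", file, " lacks column(s): ", paste(miss, collapse = ", "))
  tbl$mod_signature[is.na(tbl$mod_signature)] <- ""
  if (!is.null(channels)) {
    miss <- setdiff(channels, names(tbl))
    if (length(miss))
      stop("intensity table ", file, " lacks channel column(s): ",
           paste(miss, collapse = ", "))
  }
  chans <- intersect(names(tbl), setdiff(names(tbl), need))
  for (ch in chans) {
    tbl[[ch]] <- as.numeric(tbl[[ch]])
    if (any(is.finite(tbl[[ch]]) & tbl[[ch]] < 0))
      stop("negative intensity in channel ", ch)
  }
  tbl
}

#' Write an intensity table
#' @param tbl data.frame as produced by [makeIntensityTables()].
#' @param file output path.
#' @export
writeIntensityTable <- function(tbl, file) {
  write.table(tbl, file, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' Read channel designs from a YAML file
#'
#' The file maps run ids to channel descriptions:
#' \preformatted{
#' run1:
#'   channels: [D0, D3, D6, D9]
#'   groups:   [CONTROL, CONTROL, TREATED, TREATED]
#'   replicates: [C1, C2, T1, T2]   # optional
#' }
#'
#' @param file path to YAML.
#' @return named list of \linkS4class{ChannelDesign}, one per run.
#' @export
readChannelDesigns <- function(file) {
  y <- yaml::read_yaml(file)
  out <- lapply(names(y), function(run) {
    d <- y[[run]]
    channelDesign(run, unlist(d$channels), unlist(d$groups),
                  if (!is.null(d$replicates)) unlist(d$replicates))
  })
  setNames(out, names(y))
}

#' Write channel designs to YAML
#' @param designs list of ChannelDesign.
#' @param file output path.
#' @export
writeChannelDesigns <- function(designs, file) {
  y <- lapply(designs, function(d) list(
    channels = as.list(d@channels),
    groups = as.list(unname(d@group[d@channels])),
    replicates = as.list(unname(d@replicate[d@channels]))
  ))
  names(y) <- vapply(designs, designRunId, character(1))
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Read a two-column gene/value table
#'
#' Used for gene-level abundance (FPKM, protein copy number) and protein
#' half-life tables: TSV with header and columns \code{gene},
#' \code{value}.
#'
#' @param file path to TSV.
#' @param cap optional upper cap; values above it are clamped with a
#'   message (half-life tables conventionally cap at 100 h).
#' @param uppercase upper-case gene ids before matching (default TRUE;
#'   joining is exact string match).
#' @return named numeric vector (gene -> value).
#' @export
readGeneValueTable <- function(file, cap = NULL, uppercase = TRUE) {
  tbl <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene", "value") %in% names(tbl)))
    stop("gene/value table ", file, " needs columns: gene, value")
  g <- if (uppercase) toupper(tbl$gene) else tbl$gene
  if (anyDuplicated(g)) stop("duplicate gene ids in ", file)
  v <- as.numeric(tbl$value)
  if (any(!is.finite(v))) stop("non-finite values in ", file)
  if (!is.null(cap)) {
    n <- sum(v > cap)
    if (n) message(n, " value(s) above ", cap, " clamped to the cap")
    v <- pmin(v, cap)
  }
  setNames(v, g)
}

#' Read a gapped FASTA alignment
#'
#' For importing an externally computed multiple alignment (rows of equal
#' width, gaps as \code{-}).
#'
#' @param file path to gapped FASTA.
#' @return A \linkS4class{MultiAlignment} (score NA).
#' @export
readGappedFasta <- function(file) {
  lines <- readLines(file)
  idx <- grep("^>", lines)
  if (!length(idx)) stop("no FASTA records in ", file)
  ids <- sub("^>\\s*(\\S+).*", "\\1", lines[idx])
  ends <- c(idx[-1] - 1L, length(lines))
  rows <- vapply(seq_along(idx), function(i) {
    paste(lines[(idx[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  new("MultiAlignment", rows = setNames(rows, ids), score = NA_real_)
}

#' Write a MultiAlignment as gapped FASTA
#' @param aln a MultiAlignment.
#' @param file output path.
#' @export
writeGappedFasta <- function(aln, file) {
  rows <- alignmentRows(aln)
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(rows)) {
    writeLines(paste0(">", names(rows)[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", rows[[i]]), con)
  }
  invisible(file)
}
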
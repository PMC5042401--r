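# Global alignment and ortholog conservation scoring.
#
# The aligner is a Needleman-Wunsch / Gotoh dynamic program with affine
# gaps (gap of length g costs gapOpen + g * gapExtend) and a fully
# deterministic traceback: ties prefer the diagonal move, then up (gap
# in the second sequence), then left, so outputs are bit-reproducible.

# Generic Gotoh DP over index spaces 1..n and 1..m with a pluggable
# column score. Returns the optimal score and the aligned index paths
# (NA = gap). States: 1 = M (diagonal), 2 = X (up), 3 = Y (left).
.gotoh <- function(n, m, scoreFun, open, extend) {
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  ptrM <- matrix(0L, n + 1, m + 1); ptrX <- ptrM; ptrY <- ptrM
  M[1, 1] <- 0
  if (n > 0) {
    X[2:(n + 1), 1] <- -(open + (1:n) * extend)
    ptrX[2:(n + 1), 1] <- c(1L, rep(2L, n - 1))
  }
  if (m > 0) {
    Y[1, 2:(m + 1)] <- -(open + (1:m) * extend)
    ptrY[1, 2:(m + 1)] <- c(1L, rep(3L, m - 1))
  }
  # precompute score matrix for speed
  S <- outer(seq_len(n), seq_len(m), scoreFun)
  for (i in seq_len(n)) {
    ii <- i + 1L
    for (j in seq_len(m)) {
      jj <- j + 1L
      cand <- c(M[ii - 1, jj - 1], X[ii - 1, jj - 1], Y[ii - 1, jj - 1])
      b <- which.max(cand)               # ties: lowest index = M > X > Y
      M[ii, jj] <- cand[b] + S[i, j]
      ptrM[ii, jj] <- b
      cand <- c(M[ii - 1, jj] - open - extend,
                X[ii - 1, jj] - extend,
                Y[ii - 1, jj] - open - extend)
      b <- which.max(cand)
      X[ii, jj] <- cand[b]
      ptrX[ii, jj] <- b
      cand <- c(M[ii, jj - 1] - open - extend,
                X[ii, jj - 1] - open - extend,
                Y[ii, jj - 1] - extend)
      b <- which.max(cand)
      Y[ii, jj] <- cand[b]
      ptrY[ii, jj] <- b
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin)                # ties: diagonal > up > left
  score <- fin[state]
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 1L) {
      ai <- c(i, ai); bi <- c(j, bi)
      state <- ptrM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ai <- c(i, ai); bi <- c(NA_integer_, bi)
      state <- ptrX[i + 1, j + 1]; i <- i - 1
    } else {
      ai <- c(NA_integer_, ai); bi <- c(j, bi)
      state <- ptrY[i + 1, j + 1]; j <- j - 1
    }
  }
  list(score = score, ai = ai, bi = bi)
}

#' Optimal global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment of two protein sequences
#' under a \linkS4class{SubstitutionScheme}, computed by the Gotoh
#' affine-gap dynamic program. The traceback is deterministic
#' (diagonal, then up, then left on ties).
#'
#' @param a,b sequences (standard residues only); can be named
#'   length-1 character vectors, names become row ids.
#' @param scheme a \linkS4class{SubstitutionScheme}; default BLOSUM62
#'   with gap open 10 / extend 0.5.
#' @return A \linkS4class{MultiAlignment} with two rows and the optimal
#'   score.
#' @examples
#' s <- substitutionScheme("simple", gapOpen = 0, gapExtend = 1)
#' globalAlign("AAG", "AG", s)  # score 1
#' @export
globalAlign <- function(a, b, scheme = substitutionScheme()) {
  ids <- c(if (!is.null(names(a))) names(a)[1] else "a",
           if (!is.null(names(b))) names(b)[1] else "b")
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  .checkStandardResidues(c(a, b), "sequence")
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  mat <- scheme@matrix
  sf <- function(i, j) mat[cbind(ra[i], rb[j])]
  g <- .gotoh(length(ra), length(rb), sf, scheme@gapOpen, scheme@gapExtend)
  rowA <- ifelse(is.na(g$ai), "-", ra[ifelse(is.na(g$ai), 1L, g$ai)])
  rowB <- ifelse(is.na(g$bi), "-", rb[ifelse(is.na(g$bi), 1L, g$bi)])
  new("MultiAlignment",
      rows = setNames(c(paste(rowA, collapse = ""), paste(rowB, collapse = "")), ids),
      score = g$score)
}

#' Progressive alignment of two or three sequences
#'
#' For three sequences: the pair with the highest pairwise score is
#' aligned first; the third sequence is then aligned to the resulting
#' two-row profile (column score = mean substitution score against the
#' non-gap strategy: an existing gap in a profile row scores
#' \code{-gapExtend}), with new gap columns propagated into both profile
#' rows. More than three sequences are out of scope; import an external
#' alignment with [readGappedFasta()] instead.
#'
#' @param seqs named character vector of 2 or 3 sequences.
#' @param scheme a \linkS4class{SubstitutionScheme}.
#' @return A \linkS4class{MultiAlignment} (score NA for three rows).
#' @export
progressiveAlign <- function(seqs, scheme = substitutionScheme()) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 2L)
    return(globalAlign(seqs[1], seqs[2], scheme))
  if (length(seqs) != 3L)
    stop("progressiveAlign supports 2 or 3 sequences; import larger ",
         "alignments with readGappedFasta()")
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  scores <- vapply(pairs, function(p)
    alignmentScore(globalAlign(seqs[p[1]], seqs[p[2]], scheme)), numeric(1))
  best <- pairs[[which.max(scores)]]
  third <- setdiff(1:3, best)
  pal <- globalAlign(seqs[best[1]], seqs[best[2]], scheme)
  prof <- strsplit(unname(alignmentRows(pal)), "")
  cseq <- strsplit(unname(seqs[third]), "")[[1]]
  .checkStandardResidues(seqs[third], "sequence")
  mat <- scheme@matrix
  m <- length(prof[[1]])
  colScore <- function(i, j) {
    vapply(seq_along(i), function(k) {
      r <- cseq[i[k]]
      mean(vapply(prof, function(row) {
        ch <- row[j[k]]
        if (ch == "-") -scheme@gapExtend else mat[r, ch]
      }, numeric(1)))
    }, numeric(1))
  }
  g <- .gotoh(length(cseq), m, colScore, scheme@gapOpen, scheme@gapExtend)
  rowC <- ifelse(is.na(g$ai), "-", cseq[ifelse(is.na(g$ai), 1L, g$ai)])
  profRows <- lapply(prof, function(row)
    ifelse(is.na(g$bi), "-", row[ifelse(is.na(g$bi), 1L, g$bi)]))
  rows <- c(vapply(profRows, paste, character(1), collapse = ""),
            paste(rowC, collapse = ""))
  names(rows) <- c(names(seqs)[best], names(seqs)[third])
  rows <- rows[names(seqs)]                   # restore input order
  new("MultiAlignment", rows = rows, score = NA_real_)
}

#' Merge peptide-covered intervals on one protein
#'
#' Union of [start, end] intervals; overlapping or adjacent intervals
#' are merged. The total is the number of distinct residues covered by
#' at least one peptide.
#'
#' @param matches data.frame with \code{start}/\code{end} columns
#'   (1-based inclusive), e.g. the rows of [mapPeptides()] for one
#'   protein.
#' @return list with \code{regions} (data.frame start/end, sorted) and
#'   \code{total_residues}.
#' @examples
#' peptideRegions(data.frame(start = c(1, 5), end = c(10, 15)))
#' @export
peptideRegions <- function(matches) {
  if (!nrow(matches))
    return(list(regions = data.frame(start = integer(), end = integer()),
                total_residues = 0L))
  if ("protein_id" %in% names(matches) &&
      length(unique(matches$protein_id)) > 1L)
    stop("peptideRegions expects matches on a single protein")
  ir <- reduce(IRanges(start = matches$start, end = matches$end))
  list(regions = data.frame(start = IRanges::start(ir), end = IRanges::end(ir)),
       total_residues = sum(IRanges::width(ir)))
}

#' Percent identity over peptide-covered regions vs the whole protein
#'
#' Columns of the alignment are scored identical when every row carries
#' the same residue (a gap in any row makes the column non-identical).
#' The denominator is the number of reference residues, i.e. columns in
#' which the reference row has a residue -- so identities are "out of
#' the reference's residues". \code{identity_within_peptides} restricts
#' both numerator and denominator to columns whose reference residue
#' lies in a (merged) peptide-covered region.
#'
#' @param aln a \linkS4class{MultiAlignment}.
#' @param referenceId row name of the reference (e.g. yeast) sequence.
#' @param regions data.frame with \code{start}/\code{end} (1-based,
#'   inclusive, on the ungapped reference); overlapping regions are
#'   merged first.
#' @return list: \code{identity_whole} and \code{identity_within_peptides}
#'   (percent), \code{peptide_region_length}, \code{protein_length},
#'   \code{n_rows}.
#' @export
regionIdentity <- function(aln, referenceId, regions) {
  rows <- alignmentRows(aln)
  if (!referenceId %in% names(rows))
    stop("reference id ", referenceId, " not in alignment (rows: ",
         paste(names(rows), collapse = ", "), ")")
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  ref <- chars[[referenceId]]
  refLen <- sum(ref != "-")
  if (nrow(regions) && any(regions$start < 1 | regions$end > refLen |
                           regions$start > regions$end))
    stop("regions must lie within the reference length (", refLen, ")")
  mr <- peptideRegions(data.frame(start = regions$start, end = regions$end))
  inRegion <- rep(FALSE, refLen)
  for (i in seq_len(nrow(mr$regions)))
    inRegion[mr$regions$start[i]:mr$regions$end[i]] <- TRUE
  refPos <- cumsum(ref != "-")
  refCol <- ref != "-"
  identical_col <- Reduce(`&`, lapply(chars, function(x) x == ref)) & ref != "-"
  idWhole <- 100 * sum(identical_col[refCol]) / sum(refCol)
  sel <- refCol & inRegion[pmax(refPos, 1L)]
  idWithin <- if (any(sel)) 100 * sum(identical_col[sel]) / sum(sel) else NA_real_
  list(identity_whole = idWhole,
       identity_within_peptides = idWithin,
       peptide_region_length = mr$total_residues,
       protein_length = refLen,
       n_rows = length(rows))
}

#' Conservation report for a set of ortholog groups
#'
#' Runs [progressiveAlign()] and [regionIdentity()] for each ortholog
#' set and returns one row per set, the layout of a conservation
#' comparison table (region length, protein length, % identity within
#' peptide-covered regions and over the whole protein).
#'
#' @param orthologSets named list; each element a named character vector
#'   of 2-3 ortholog sequences, first element the reference.
#' @param regionsBySet named list of region data.frames (start/end on
#'   the reference), keyed like \code{orthologSets}.
#' @param scheme a \linkS4class{SubstitutionScheme}.
#' @return data.frame with columns \code{set}, \code{peptide_aa},
#'   \code{protein_aa}, \code{identity_within}, \code{identity_whole}.
#' @export
conservationReport <- function(orthologSets, regionsBySet,
                               scheme = substitutionScheme()) {
  rows <- lapply(names(orthologSets), function(id) {
    seqs <- orthologSets[[id]]
    aln <- progressiveAlign(seqs, scheme)
    ri <- regionIdentity(aln, names(seqs)[1], regionsBySet[[id]])
    data.frame(set = id,
               peptide_aa = ri$peptide_region_length,
               protein_aa = ri$protein_length,
               identity_within = ri$identity_within_peptides,
               identity_whole = ri$identity_whole,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
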
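# Synthetic-study generator. Emulates the statistical structure a
# label-based peptidomics analysis assumes: peptides drawn
# preferentially from abundant proteins, tunable enrichment of protein
# termini, P1 residue preferences at the upstream cleavage site, and
# 4-channel intensity data with multiplicative log-normal noise around
# known fold changes. Everything is deterministic given (seed, config);
# each stage derives its own sub-seed so stages can be regenerated
# independently.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed %% .Machine$integer.max)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Default residue frequencies for simulated proteomes
#'
#' Background amino-acid frequencies of intracellular proteins (from the
#' packaged background-composition table, see
#' [backgroundComposition()]), normalized to sum to 1.
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
defaultResidueFrequencies <- function() {
  bg <- backgroundComposition()
  setNames(bg$intracellular_pct / sum(bg$intracellular_pct), bg$residue)
}

#' Configuration of a synthetic peptidome study
#'
#' Defaults describe a study of the scale and structure typical of a
#' single-organism quantitative peptidomics experiment: about 300
#' peptides from a pool of abundant proteins (mean protein length 353,
#' median-targeting sd 150), peptide lengths around 15 residues, strong
#' terminal enrichment (theta = 0.29, i.e. ~29% of peptides forced onto
#' a protein terminus over the <1% uniform expectation), P1 preferences
#' dominated by hydrophobic > basic > acidic residues with Pro rare,
#' log-normal protein abundance, two 4-plex runs (two control + two
#' treated channels) with 20% CV multiplicative noise and two charge
#' states per peptide.
#'
#' @param seed integer master seed; all stages derive sub-seeds from it.
#' @param nProteins number of proteins in the simulated proteome.
#' @param lengthMean,lengthSd,lengthMin protein-length distribution
#'   (truncated normal, residues).
#' @param residueFreqs named residue probability vector (must sum to 1).
#' @param nPeptides number of peptides to draw.
#' @param pepLenMean,pepLenSd,pepLenMin,pepLenMax peptide-length
#'   distribution (truncated normal, residues).
#' @param theta probability mass forced onto terminal windows (0..1).
#' @param p1Weights named relative weights over P1 categories
#'   (ACIDIC/BASIC/HYDROPHOBIC/PRO/OTHER) for the N-side cleavage site.
#' @param abundanceMeanlog,abundanceSdlog log-normal protein abundance.
#' @param foldChange multiplier applied to treated channels of affected
#'   peptides.
#' @param changedFraction fraction of peptides carrying the fold change
#'   (the rest have true fold 1).
#' @param noiseCv coefficient of variation of the multiplicative
#'   log-normal measurement noise.
#' @param nRuns number of LC-MS runs.
#' @param chargeStates charge states observed per peptide.
#' @param channels,controlChannels label channels and which of them are
#'   controls.
#' @param acetylProb probability that an N-terminal peptide is
#'   N-acetylated.
#' @return list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nProteins = 500L,
                      lengthMean = 353, lengthSd = 150, lengthMin = 50,
                      residueFreqs = defaultResidueFrequencies(),
                      nPeptides = 300L,
                      pepLenMean = 15, pepLenSd = 4, pepLenMin = 7, pepLenMax = 30,
                      theta = 0.29,
                      p1Weights = c(ACIDIC = 0.11, BASIC = 0.22,
                                    HYDROPHOBIC = 0.50, PRO = 0.01, OTHER = 0.16),
                      abundanceMeanlog = 0, abundanceSdlog = 1.5,
                      foldChange = 1, changedFraction = 0,
                      noiseCv = 0.2,
                      nRuns = 2L, chargeStates = 2L,
                      channels = c("D0", "D3", "D6", "D9"),
                      controlChannels = c("D0", "D3"),
                      acetylProb = 0.6) {
  stopifnot(theta >= 0, theta <= 1, noiseCv >= 0,
            pepLenMin >= 1, pepLenMax >= pepLenMin,
            lengthMin >= pepLenMin)
  if (abs(sum(residueFreqs) - 1) > 1e-6)
    stop("residueFreqs must sum to 1")
  if (!setequal(names(p1Weights), P1_CATEGORIES))
    stop("p1Weights must be named by the P1 categories")
  if (!all(controlChannels %in% channels))
    stop("controlChannels must be a subset of channels")
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  cfg
}

.rtruncnorm <- function(n, mean, sd, lo, hi = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a proteome
#'
#' Protein lengths are drawn from a truncated normal; residues are
#' i.i.d. from the configured frequencies with the first residue forced
#' to Met (translation initiator); per-protein abundance is log-normal;
#' location/function categories are assigned with frequencies typical of
#' an intracellular precursor pool (cytosol-dominated).
#'
#' @param config a [simConfig()].
#' @return A \linkS4class{Proteome} with abundance metadata.
#' @export
makeProteome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  if (config$lengthMin > config$lengthMean + 6 * config$lengthSd)
    stop("infeasible protein length bounds")
  .withSeed(config$seed + 101L, {
    n <- config$nProteins
    lens <- .rtruncnorm(n, config$lengthMean, config$lengthSd, config$lengthMin)
    freqs <- config$residueFreqs[AA_STANDARD]
    freqs[is.na(freqs)] <- 0
    seqs <- vapply(lens, function(L) {
      paste0("M", paste(sample(AA_STANDARD, L - 1, replace = TRUE, prob = freqs),
                        collapse = ""))
    }, character(1))
    ids <- sprintf("SP%04d", seq_len(n))
    locs <- sample(c("cytosol", "nucleus", "mitochondrion", "vacuole",
                     "ER", "other"), n, replace = TRUE,
                   prob = c(0.50, 0.15, 0.15, 0.10, 0.05, 0.05))
    funcs <- sample(c("metabolism", "translation", "chaperone", "redox",
                      "trafficking", "proteolysis", "other"), n,
                    replace = TRUE,
                    prob = c(0.35, 0.20, 0.12, 0.10, 0.08, 0.05, 0.10))
    ab <- rlnorm(n, config$abundanceMeanlog, config$abundanceSdlog)
    Proteome(setNames(seqs, ids), gene = sprintf("GENE%04d", seq_len(n)),
             location = locs, func = funcs, abundance = ab)
  })
}

#' Simulate a peptidome from a proteome
#'
#' Source proteins are drawn with probability proportional to abundance.
#' With probability theta a peptide is forced onto a protein terminus
#' (N or C with equal odds); otherwise its window start is uniform over
#' all windows. For non-N-terminal windows the upstream (P1) residue is
#' subjected to rejection sampling against the configured category
#' weights (accept with probability weight/max(weight); after 100
#' rejected draws the window is accepted as-is so pathological weight
#' settings terminate). Peptide lengths come from the configured
#' truncated normal, clipped to the protein. N-terminal peptides are
#' acetylated with probability \code{acetylProb}. Masses in the emitted
#' table are computed with [monoisotopicMass()], not simulated.
#'
#' @param proteome a \linkS4class{Proteome} (needs abundance metadata;
#'   missing abundance means uniform).
#' @param config a [simConfig()].
#' @return list with \code{peptides} (peptide table including
#'   coordinates and flanks) and \code{truth} (per-peptide ground truth:
#'   source protein, coordinates, terminal flag, true fold change).
#' @export
makePeptidome <- function(proteome, config) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(config$seed + 202L, {
    n <- config$nPeptides
    lens <- proteinLengths(proteome)
    seqs <- proteinSequences(proteome)
    genes <- proteinGenes(proteome)
    ab <- proteinMeta(proteome)$abundance
    if (is.null(ab)) ab <- rep(1, length(proteome))
    w <- config$p1Weights / max(config$p1Weights)
    eligible <- which(lens >= config$pepLenMin)
    if (!length(eligible)) stop("no protein long enough for the peptide length minimum")
    pick <- eligible[sample.int(length(eligible), n, replace = TRUE,
                                prob = ab[eligible])]

    start <- integer(n); k <- integer(n); terminal <- logical(n)
    seen <- new.env(hash = TRUE)
    for (i in seq_len(n)) {
      L <- unname(lens[pick[i]])
      drawWindow <- function() {
        ki <- .rtruncnorm(1, config$pepLenMean, config$pepLenSd,
                          config$pepLenMin, min(config$pepLenMax, L))
        forced <- runif(1) < config$theta
        tries <- 0L
        repeat {
          st <- if (forced) {
            if (runif(1) < 0.5) 1L else L - ki + 1L
          } else sample.int(L - ki + 1L, 1L)
          if (st == 1L) break                     # no N-side site to weight
          p1 <- substr(seqs[pick[i]], st - 1L, st - 1L)
          acc <- w[[as.character(classifyP1(p1))]]
          tries <- tries + 1L
          if (runif(1) < acc || tries >= 100L) break
        }
        c(st, ki)
      }
      # redraw on sequence collisions so emitted peptides are unique keys
      # (degenerate configs may exhaust the retries and keep a duplicate)
      for (attempt in 1:25) {
        sk <- drawWindow()
        cand <- substr(seqs[pick[i]], sk[1], sk[1] + sk[2] - 1L)
        if (is.null(seen[[cand]])) break
      }
      seen[[cand]] <- TRUE
      start[i] <- sk[1]; k[i] <- sk[2]
      terminal[i] <- sk[1] == 1L || sk[1] + sk[2] - 1L == L
    }
    end <- start + k - 1L
    pep <- substr(seqs[pick], start, end)
    nterm <- start <= 2L
    acet <- nterm & runif(n) < config$acetylProb
    fold <- rep(1, n)
    nChanged <- round(config$changedFraction * n)
    if (nChanged > 0)
      fold[sample.int(n, nChanged)] <- config$foldChange
    up <- ifelse(start == 1L, TERMINUS_MARK,
                 substr(seqs[pick], start - 1L, start - 1L))
    dn <- ifelse(end == lens[pick], TERMINUS_MARK,
                 substr(seqs[pick], end + 1L, end + 1L))
    peptides <- data.frame(
      sequence = pep,
      n_acetyl = as.integer(acet),
      ox_met = "",
      gene = unname(genes[pick]),
      protein_id = proteinIds(proteome)[pick],
      start = start, end = end,
      upstream = up, downstream = dn,
      mass = round(monoisotopicMass(pep, nAcetyl = acet), 5),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      peptide = seq_len(n),
      sequence = pep,
      protein_id = proteinIds(proteome)[pick],
      start = start, end = end,
      terminal = terminal,
      true_fold = fold,
      abundance = unname(ab[pick]),
      stringsAsFactors = FALSE
    )
    list(peptides = peptides, truth = truth)
  })
}

#' Simulate multiplexed intensity tables
#'
#' Per run, each peptide gets a log-normal base intensity linked to its
#' precursor abundance; control channels observe base x noise, treated
#' channels base x true fold x noise, independently per channel and
#' charge state, with multiplicative log-normal noise of the configured
#' CV (mean 1).
#'
#' @param peptidome result of [makePeptidome()].
#' @param config a [simConfig()].
#' @return list with \code{intensities} (long data.frame in the
#'   intensity-table dialect, all runs), \code{designs} (list of
#'   \linkS4class{ChannelDesign}) and \code{truth}.
#' @export
makeIntensityTables <- function(peptidome, config) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(config$seed + 303L, {
    tr <- peptidome$truth
    pep <- peptidome$peptides
    n <- nrow(tr)
    sigma <- if (config$noiseCv > 0) sqrt(log(1 + config$noiseCv^2)) else 0
    noise <- function(m) {
      if (sigma == 0) matrix(1, nrow(m), ncol(m))
      else matrix(rlnorm(length(m), -sigma^2 / 2, sigma), nrow(m))
    }
    chans <- config$channels
    ctrl <- chans %in% config$controlChannels
    mods <- ifelse(pep$n_acetyl == 1, "ac", "")
    rows <- list()
    for (r in seq_len(config$nRuns)) {
      base <- rlnorm(n, log(tr$abundance) + 8, 0.5)
      for (z in seq_len(config$chargeStates)) {
        m <- matrix(base, n, length(chans))
        m[, !ctrl] <- m[, !ctrl] * tr$true_fold
        m <- m * noise(m)
        df <- data.frame(run_id = sprintf("run%02d", r),
                         sequence = tr$sequence,
                         mod_signature = mods,
                         charge = z + 1L,
                         stringsAsFactors = FALSE)
        for (ci in seq_along(chans)) df[[chans[ci]]] <- m[, ci]
        rows[[length(rows) + 1L]] <- df
      }
    }
    intensities <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    designs <- lapply(seq_len(config$nRuns), function(r)
      channelDesign(sprintf("run%02d", r), chans,
                    ifelse(ctrl, "CONTROL", "TREATED")))
    names(designs) <- vapply(designs, designRunId, character(1))
    list(intensities = intensities, designs = designs, truth = tr)
  })
}

#' Simulate a complete study and optionally write its files
#'
#' Chains [makeProteome()], [makePeptidome()] and
#' [makeIntensityTables()]. With \code{dir} set, writes the file set the
#' analysis functions consume -- \code{proteome.fasta},
#' \code{peptides.tsv}, \code{intensities.tsv}, \code{design.yaml} --
#' plus \code{truth.json} for harnesses. Identical (seed, config) give
#' byte-identical files.
#'
#' @param config a [simConfig()].
#' @param dir optional output directory (created if needed).
#' @return list with \code{proteome}, \code{peptides}, \code{truth},
#'   \code{intensities}, \code{designs} (and \code{files} if written).
#' @export
simulateStudy <- function(config = simConfig(), dir = NULL) {
  prot <- makeProteome(config)
  pd <- makePeptidome(prot, config)
  it <- makeIntensityTables(pd, config)
  out <- list(proteome = prot, peptides = pd$peptides, truth = pd$truth,
              intensities = it$intensities, designs = it$designs)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      proteome = file.path(dir, "proteome.fasta"),
      peptides = file.path(dir, "peptides.tsv"),
      intensities = file.path(dir, "intensities.tsv"),
      design = file.path(dir, "design.yaml"),
      truth = file.path(dir, "truth.json")
    )
    writeProteome(prot, files$proteome)
    writePeptideTable(pd$peptides, files$peptides)
    writeIntensityTable(it$intensities, files$intensities)
    writeChannelDesigns(it$designs, files$design)
    jsonlite::write_json(pd$truth, files$truth, digits = NA)
    out$files <- files
  }
  out
}
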
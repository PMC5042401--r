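# Independent oracles and shared fixtures for the test suite.

# Brute-force global-alignment score: enumerate every monotone alignment
# path (diagonal / up / left moves), scoring affine gaps incrementally
# (a gap run of length g costs open + g * extend). Exponential on
# purpose -- it shares no code with the DP implementation.
bruteAlignScore <- function(a, b, mat, open, extend) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  best <- -Inf
  recurse <- function(i, j, acc, last) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < n && j < m)
      recurse(i + 1, j + 1, acc + mat[ra[i + 1], rb[j + 1]], "D")
    if (i < n)
      recurse(i + 1, j, acc - extend - if (last == "U") 0 else open, "U")
    if (j < m)
      recurse(i, j + 1, acc - extend - if (last == "L") 0 else open, "L")
  }
  recurse(0, 0, 0, "D")
  best
}

# Hand-computed pooled-variance two-sample t-test (Student), the oracle
# for poolAndTest.
pooledT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

simpleScheme <- function(gapOpen = 0, gapExtend = 1) {
  substitutionScheme("simple", match = 1, mismatch = -1,
                     gapOpen = gapOpen, gapExtend = gapExtend)
}

# Tiny mixed proteome used across mapping/census tests.
testProteome <- function() {
  Proteome(
    c(P1 = "AASTLPEIYEKG",        # hosts STLPEIYEK internally
      P2 = "MAVKTTAGW",           # Met-initiated
      P3 = "MKV",                 # whole-protein edge case
      P4 = "AAAA",                # repeat: multiple matches
      P5 = "MSSAKGATPEELVNKWHE"),  # matureStart 4 models a cleaved precursor
    gene = c("ADH1", "ENO2", "TDH1", "TDH3", "PREC"),
    location = c("cytosol", "cytosol", "nucleus", NA, "vacuole"),
    func = c("metabolism", "metabolism", "redox", NA, "proteolysis"),
    matureStart = c(NA, NA, NA, NA, 4)
  )
}

# Four-plex design with two control and two treated channels.
testDesign <- function(run = "r1") {
  channelDesign(run, c("D0", "D3", "D6", "D9"),
                c("CONTROL", "CONTROL", "TREATED", "TREATED"))
}
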
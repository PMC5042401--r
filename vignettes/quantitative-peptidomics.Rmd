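---
title: "Quantitative peptidomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative peptidomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptidomics)
```

## The measurement model

Intracellular peptidomics detects endogenous peptides — products of
cellular proteolysis, dominated by the proteasome — rather than peptides
produced by a deliberate tryptic digest. Two consequences shape the
analysis.

First, peptides carry no cleavage-specificity constraint, so a peptide
sequence is located in the proteome by exact substring search over every
protein, and all occurrences are kept (paralogous genes can share exact
stretches). When the identification table annotates a gene, the
occurrence in that gene is marked *canonical* and used for census
statistics, so each peptide is counted once. Isoleucine and leucine are
treated as distinct characters: identifications come from MS/MS search
engines that committed to one of them, and collapsing I/L here would
silently change mapping multiplicities. Coordinates are 1-based and
inclusive throughout, matching how residue positions are quoted in the
field ("residue 1 is the initiator Met").

Second, quantification is relative and per-run. Each LC-MS run carries up
to four TMAB-labeled channels (D0/D3/D6/D9 — 0 to 9 deuteriums on a
trimethylammoniumbutyryl amine tag), conventionally two control and two
treated biological replicates. For a peptide seen at several charge
states, per-channel peak intensities are averaged across states first.
Each detected channel is then divided by the mean of the detected
*control* channels of the same run:

$$r_c = \frac{I_c}{\overline{I}_{\mathrm{ctrl}}}.$$

This forces the control ratios of every run to average to exactly 1 (an
algebraic identity the test suite checks at 1e-12) and makes ratios
comparable across runs, which is what permits pooling control replicates
across experiments to raise the replicate count. Undetected channels stay
"not detected" (ND) and never enter any mean; an observation with no
detected control channel cannot be normalized and is flagged
unquantifiable rather than dropped silently.

## Differential testing

Pooled control and treated ratios are compared per peptide with a
two-sided two-sample Student's t-test with pooled variance
(df = $n_1+n_2-2$), the convention for this kind of small-$n$ table; a
Benjamini–Hochberg adjusted column is emitted alongside but the
significance tiers (p < 0.05 / 0.01 / 0.001) follow the raw p-values,
mirroring how such tables are reported. Fold-change classes use strict
inequalities (> 2, < 0.5), so a treated mean of exactly 2 is *within*.

Numerical edge cases are resolved explicitly rather than left to produce
infinities on small fixtures: if both groups are constant (at a relative
tolerance of 1e-10) with equal means the result is t = 0, p = 1; constant
groups with unequal means are flagged `degenerate` with p absent.
Peptides quantifiable in fewer than `minRuns` runs (default 3, the usual
"detected in three or more runs" rule for pooled tables) are kept in
per-run outputs but not tested.

One property of this design is worth knowing: because each run's control
ratios are self-normalized (they sum to twice their mean of 1), the
control group's pooled variance is structurally smaller than the treated
group's, and the pooled-variance t-test then runs slightly *anti*-
conservative — the realized false-positive rate at p < 0.05 sits a little
above the nominal 5%. The acceptance script quantifies this: it simulates
a null study (true fold 1, 20% CV, 2 runs × 2+2 channels, 1000 peptides)
and reports the realized rate. Users wanting exact nominal size should
treat the tiers as descriptive, as the tables they reproduce do.

## Terminal classification and the analytic baseline

Peptides are classed N-terminal (starting at residue 1, or at residue 2
of a Met-initiated protein — initiator-Met excision removes the Met
co-translationally, so such peptides still represent the protein's
N-terminus — or at an annotated mature-protein N-terminus), C-terminal
(containing the last residue), or internal. The classes are exclusive; a
peptide that is both N- and C-terminal (a whole-protein match) is
classified N-terminal. This precedence is our choice — published terminal
percentages do not say how a both-termini peptide would be counted, and
none occurs in the tables this package reproduces — and it is applied
consistently by the census and the simulator.

The null baseline for terminal enrichment is analytic: a protein of
length $L$ has $W = L - k + 1$ windows of length $k$, at most two of
which touch a terminus, so uniform sampling gives a terminal fraction of
$\min(2, W)/W$ — about 0.6% at $L = 350$, $k = 15$, and below 1% for all
$L$ in 300–400. Observed terminal fractions an order of magnitude above
this are positional enrichment, not sampling accident.

Cleavage sites are reported with two denominators because published
preference figures mix them: *per site* (all N-side and C-side sites
pooled) and *per peptide* (a peptide counts once per category if any of
its sites qualifies). Both are always computed; consumers pick the one
matching the quantity they compare against.

## The simulator: what it emulates and what it does not

`simConfig()` defaults describe the study conditions this package was
built around: proteins with truncated-normal lengths (mean 353, sd 150,
min 50 residues — the scale of precursor pools observed in peptidomics),
background residue frequencies from the packaged intracellular-protein
composition table, log-normal protein abundance (sdlog 1.5, so a few
proteins dominate, as observed), ~300 peptides of length ~15 (sd 4,
range 7–30), terminal enrichment θ = 0.29 (matching the ~29% terminal
fraction real peptidomes show against the <1% baseline), P1 category
weights hydrophobic 0.50 / basic 0.22 / acidic 0.11 / Pro 0.01 / other
0.16 (the observed per-peptide cleavage preferences, used as generative
weights), two 4-plex runs with two charge states and 20% CV
multiplicative log-normal noise (mean-1, $\sigma^2 = \log(1+CV^2)$), and
N-terminal acetylation probability 0.6 for N-terminal peptides (the
scale of proteome-wide N-terminal acetylation). Peptide masses in
emitted tables are computed from the sequence, never simulated.

Sampling is abundance-weighted at the protein level; with probability θ
the window is forced onto a terminus (N or C with equal odds), otherwise
the start is uniform; for non-N-terminal windows the upstream (P1)
residue is accepted by rejection sampling against the category weights
(accept with probability weight/max weight, at most 100 redraws).
Emitted peptide sequences are de-duplicated by redrawing (25 attempts)
so that the (sequence, modification) quantification key is unique;
degenerate configurations may still emit duplicates.

Determinism: one master seed, with fixed per-stage sub-seeds
(proteome/peptidome/intensities) so stages regenerate independently;
identical (seed, config) give byte-identical files, and the generator
saves and restores the caller's RNG state.

What the simulator does *not* model — and therefore what passing tests do
not establish about real data: missing peaks (every channel is observed),
retention-time or ionization effects, isotope-cluster interference,
charge-state-dependent intensity, identification error, and
abundance-dependent detection probability beyond the protein-level
weighting. Recovery results on simulated data validate the estimator's
algebra and its sampling behavior under the stated noise model, not
robustness to those instrument effects.

## Alignment and conservation scoring

The global aligner is a Needleman–Wunsch/Gotoh dynamic program with
affine gaps costing `gapOpen + g * gapExtend` for a gap of length g.
Defaults are BLOSUM62 with open 10 / extend 0.5 — standard practice for
protein global alignment; the scheme is recorded with the output because
published conservation percentages rarely state their alignment
parameters, so identity values should be expected to approximate, not
exactly match, any particular published table. The traceback is
deterministic: ties prefer the diagonal move, then up, then left, and
within a move the diagonal-state predecessor, so outputs are
bit-reproducible. Progressive alignment covers the two- or three-ortholog
case (align the closest pair by score, then align the third sequence to
the two-row profile, scoring an existing profile gap at −gapExtend and
propagating new gap columns into both rows); larger alignments are
imported from external tools as gapped FASTA.

Percent identity uses the reference (first) sequence's residues as the
denominator; a gap in any row makes a column non-identical. "Within
peptides" restricts both numerator and denominator to columns whose
reference residue falls in the merged peptide-covered intervals
(overlapping or adjacent intervals are unioned first).

Validation of the aligner is by brute force: an enumeration oracle walks
every monotone alignment path and scores gap runs directly, sharing no
code with the DP. The test suite sweeps *all* pairs of sequences of
length ≤ 3 over a 4-letter alphabet (7056 pairs) and a seeded random
sample of longer pairs up to length 6, under both linear and affine
penalties; an exhaustive sweep at length 6 (~30 million pairs against an
exponential oracle) is not computable in reasonable time, and the
complete short sweep plus random long sample covers the same recurrence
paths. BLOSUM62 affine scores are additionally cross-checked against the
independent Biostrings implementation on random protein pairs.

## Numerical and I/O conventions

* Percent tables carry exact `fraction` columns (summing to 1) next to
  display-rounded `percent` columns (composition to 1 decimal, terminal
  tallies to the nearest integer), so rounding never propagates.
* Monoisotopic masses are assembled from CODATA atomic masses and
  elemental residue formulas (water 18.01056; acetyl +42.01057; Met
  oxidation +15.99491), keeping modification and label deltas consistent
  with one atom table. TMAB label masses (D0 +128.10754; D3/D6/D9 adding
  3/6/9 × (²H−¹H)) are provided as constants but never added to table
  masses, which are conventionally unlabeled.
* Nonstandard residue codes (B, Z, X, U) are rejected with an error
  everywhere; silently skipping them would corrupt composition and mass
  statistics.
* Abundance ranking is by descending value with stable ties (input
  order), making bin counts reproducible and invariant under strictly
  monotone transforms of the values; gene joining is exact string match
  after upper-casing, never fuzzy.
* Half-lives are capped at 100 h on load (the convention of the turnover
  datasets this analysis consumes), with the number of clamped values
  reported.

## Problem sizes

The shipped test suite and acceptance script run at the scale the
methods are designed for: census and mapping fixtures of 5–80 peptides;
simulated studies of 500 peptides (fold-change recovery) and 1000
peptides (test size), each 2 runs × 4 channels × 2 charge states;
10,000 peptides for the terminal-enrichment null; and the alignment
sweep described above. The full suite completes in about a minute on one
CPU.

## Known limitations

* Only 2–3 sequences are aligned natively; conservation over larger
  ortholog sets requires an imported alignment.
* The per-peptide cleavage tally needs the caller to supply the total
  peptide count when some peptides produce no sites (whole-protein
  matches), otherwise the denominator defaults to peptides with sites.
* The census reproduction of published supplementary peptide tables
  requires those tables, which are journal supplements and not
  redistributable here; the corresponding acceptance check documents the
  expected values and runs once the user drops the converted TSVs under
  `inst/extdata/supplementary/`.
* The pooled t-test's mild anti-conservatism under self-normalized
  controls (above) is inherent to the published design being reproduced,
  not corrected away.
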
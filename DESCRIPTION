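Package: peptidomics
Title: Quantitative Peptidomics of Intracellular Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mass-spectrometry-based quantitative peptidomics of
    endogenous intracellular peptides. Quantifies relative peptide levels
    from multiplexed isotopic-label (TMAB D0/D3/D6/D9) peak intensities
    with charge-state averaging, control-mean normalization, cross-run
    pooling and differential t-statistics; characterizes a peptidome by
    peptide-to-proteome mapping, terminal classification, cleavage-site
    P1 preferences, amino-acid composition and mass distribution; relates
    precursor proteins to gene-level abundance ranks and protein half-life
    distributions; scores ortholog conservation of peptide-covered protein
    regions by global alignment; and simulates complete labeled peptidome
    studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
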
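Package: sgescreen
Title: Simulation and Analysis of Saturation Genome Editing Depletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring variant effects from saturation genome editing
    (SGE) depletion screens in essential-gene cell lines. Provides read-level
    calling of programmed single-nucleotide variants and 3-bp deletions
    against a target specification with fixed (HDR-marker) edits and
    homopolymer length tolerance, library- and replicate-level quality
    control, LOESS correction of cut-site position effects, per-day log2
    fold-change fitness scores and RNA-abundance scores, two-component
    Gaussian mixture functional classification with derived score thresholds,
    and clinical calibration: OddsPath evidence strengths, ACMG/AMP point
    combination, ROC/AUC, and case-control odds ratios. A synthetic-data
    generator with known ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
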
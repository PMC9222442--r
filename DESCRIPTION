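Package: dexscreen
Title: Transcriptional Biomarker Screening for Illicit Dexamethasone
    Treatment in Veal Calves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for screening veal-calf muscle samples for
    illicit low-dose dexamethasone treatment from qPCR gene-expression
    panels measured on formalin-fixed paraffin-embedded (FFPE) tissue,
    optionally fused with muscle-fibre morphometry. Covers quantification
    cycle (Cq) preprocessing with a late-Cq cutoff and replicate outlier
    screening, reference-gene selection by geNorm and NormFinder
    stability measures, delta-delta-Cq relative quantification with
    ANOVA/Tukey differential-expression statistics, fibre-diameter
    morphometry summaries, and multivariate classification by PCA,
    PLS-DA and supervised Kohonen self-organising maps with stratified
    holdout cross-validation and per-class performance metrics. Includes
    a synthetic-study generator emulating FFPE-degraded qPCR data so the
    whole pipeline is testable without access to confidential animal
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
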
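Package: proteocensus
Title: Absolute Proteome Quantification by Stable-Isotope Dilution SRM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for census-style absolute protein
    quantification of a proteome by selected reaction monitoring (SRM)
    with QconCAT stable-isotope-labeled internal standards. Covers
    in-silico assay design (tryptic digestion, quantotypic peptide
    selection, transition selection, acquisition scheduling), decoy-based
    peak-group scoring with target-decoy FDR control, isotope-dilution
    copies-per-cell quantification with QC filtering, Type A/B/C outcome
    classification and sibling-peptide reconciliation, cross-dataset
    comparison (ppm rescaling, Spearman correlation, hierarchical
    clustering, M-versus-A), and proteome-transcriptome integration
    (translational efficiency, total-proteome extrapolation, correction
    for attenuation, model-II log-log slopes, and a forward-selected
    multivariate translation model). A synthetic-data generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
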
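Package: kdconcord
Title: Cross-Model Knockdown Concordance Transcriptomics and Survival Screening
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for characterising a gene-knockdown
    transcriptional program shared across two cell-line models: counts-per-million
    normalisation with log2 transform, protein-coding restriction, global and
    cell-line-adjusted principal component analysis, per-line Welch differential
    expression with offset log2 fold changes, a cross-model concordance core
    signature, a from-scratch preranked gene set enrichment analysis
    (running-sum enrichment score, gene-permutation null, NES, BH FDR), and
    z-scored heatmap/module matrices. A companion survival module implements
    Kaplan-Meier estimation, the log-rank test, single-covariate proportional
    hazards fitting with Efron tie handling, expression dichotomisation, and a
    multi-gene hazard-ratio screen. A negative-binomial count simulator and an
    exponential survival-cohort simulator generate data with the structure the
    analysis assumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
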
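Package: coupledchains
Title: Electrical-Coupling Motif Analysis for Multipatch Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing simultaneous multipatch recordings of
    locus coeruleus noradrenergic neurons: intrinsic electrophysiology
    feature extraction from current-step protocols, gap-junction coupling
    coefficient estimation and connection classification, somatodendritic
    morphology quantification (soma/dendrite bipolarity, Sholl profiles),
    and motif-level null-model inference (random, cell-type-specific,
    distance-restricted, and chain-rule generative models with Monte
    Carlo prediction intervals). Includes a synthetic-data module that
    emulates the statistical structure of multipatch recording cohorts
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    nnet,
    minpack.lm,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
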
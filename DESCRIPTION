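Package: marrowscape
Title: Quantifying Immune Remodeling of the Myeloma Bone Marrow from Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying bone-marrow immune
    remodeling in multiple myeloma from single-cell RNA-seq and bulk TCR
    data. Implements per-cell dissimilarity scoring against a healthy
    reference via iterated balanced k-nearest-neighbour neighbourhood
    composition, calibrated aberrant/healthy-like cell-state classification,
    malignant plasma-cell calling from genome-windowed expression profiles
    refined by immunoglobulin light-chain restriction, cell-type
    compositional analysis, binned-control gene-module scoring, rule-based
    T-cell gating, and TCR repertoire clonality and overlap metrics. A
    synthetic cohort generator with planted ground truth makes the whole
    pipeline testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
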
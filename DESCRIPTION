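Package: metabosig
Title: Untargeted Metabolomics Signature Discovery with Stability-Selected PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for untargeted LC-MS feature tables
    from case-control cohort studies: QC/blank-based feature filtering,
    below-minimum imputation, probabilistic quotient normalization, PCA-based
    outlier gating with Hotelling T2 and Q statistics, class balancing by
    onion D-optimal design on PCA scores, PLS2 classification with VIP-driven
    stability selection and out-of-bag Matthews correlation, a
    classifier-agnostic repeated cross-validation and permutation-testing
    harness, per-feature fold-change / Mann-Whitney / Storey q-value
    screening, and cohort-metadata tests. Includes a synthetic-data generator
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mixOmics,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
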
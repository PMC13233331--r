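Package: hemomil
Title: Attention-Based Multiple-Instance Learning for Blood Smear Cytomorphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient-level classification of hematological disease classes from
    bags of single-cell embedding vectors, using a permutation-invariant
    transformer aggregator with cell-level attention. A multi-task head predicts
    probabilities for eight coarse diagnostic classes together with the
    patient's hemoglobin value. Includes a configurable three-level diagnostic
    label hierarchy, stratified k-fold cross-validation with probability-level
    ensembling, malignancy triage with a tunable biopsy-recommendation
    threshold, an evaluation suite (confusion analysis, top-k accuracy, AUROC,
    expected calibration error, hemoglobin agreement, probability-vs-cell-ratio
    correlations), per-cell attention explanations, and a synthetic cohort
    generator with class-conditioned cell-type mixtures for end-to-end testing
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
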
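Package: stratomics
Title: Integrated Clinical-Proteomic Machine-Learning Stratification
Version: 0.1.0
Authors@R:
    person("Maintainer", "Stratomics", email = "maintainer@stratomics.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for integrated clinical-proteomic
    patient stratification. Implements label-free proteomics post-processing
    (log2 transform, valid-value filtering, downshifted-normal imputation,
    quantile normalization, permutation-FDR differential testing), kNN
    imputation and leakage-safe standardization of clinical tables, consensus
    feature selection (repeated stratified cross-validation with internal
    bootstrap resampling, recursive feature elimination, and correlated-cluster
    deduplication), a five-classifier benchmark (Gaussian naive Bayes, linear
    SVM, random forest, extremely randomized trees, AdaBoost) with permutation
    significance tests and consensus importance ranking, ROC/AUC biomarker
    panel filtering with Youden cutoffs, and consensus misclassification-based
    re-stratification. Ships a seeded synthetic cohort generator with
    intensity-dependent missingness so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
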
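Package: anmda
Title: Anti-Noise Prediction of miRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a curated
    list of experimentally verified pairs. Features for each (miRNA, disease)
    pair are built from MeSH-style disease semantic similarity, miRNA
    functional similarity and Gaussian interaction-profile kernels; reliable
    negative examples are drawn from the undetected pool by k-means
    cluster-balanced sampling; and a bootstrap-subsampled ensemble of
    gradient-boosted tree (or kNN, multilayer-perceptron, logistic) base
    learners averages member probabilities to smooth hidden-positive label
    noise. Includes repeated stratified cross-validation, a label-noise
    injection experiment harness, a noise-rate estimator, and synthetic-data
    generators so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
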
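Package: oudel
Title: Ornstein-Uhlenbeck Models of Expression Evolution After Gene Deletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of gene expression after a gene deletion
    event on a two-species phylogeny as an Ornstein-Uhlenbeck process, and
    predicts whether the deleted duplicate was functionally redundant
    (shared expression optimum) or unique (distinct optimum), together with
    the expression optima and the log stationary variance of the process.
    Provides a simulator with rejection sampling against empirical
    expression bounds for building labelled training data; four supervised
    architectures (feed-forward neural network, gradient-boosted trees,
    random forest, radial-basis support vector machine) for classification
    and multi-output regression with cross-validated hyperparameter
    selection and sampling-based Shapley feature importance; a
    maximum-likelihood baseline that classifies events by a likelihood-ratio
    test on nested Ornstein-Uhlenbeck models; and evaluation tools such as
    ROC curves, power at fixed false-positive rate, confusion matrices,
    parameter-error distributions, parameter-region performance surfaces and
    noise-robustness experiments, plus helpers for applying trained
    predictors to empirical deletion-event expression tables.
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
    rlang,
    ggplot2,
    generics,
    ranger,
    xgboost,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mvtnorm,
    withr
Config/testthat/edition: 3
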
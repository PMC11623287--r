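Package: probfs
Title: Probability-Based Feature Generation for Suicide-Risk Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for binary text classification of mental-health related
    social-media posts, centered on ProBFS: a compact probability-based
    feature set in which per-class probabilities from TF-IDF-trained
    logistic-regression and linear support-vector-machine base learners
    become a four-column representation for downstream classifiers.
    Includes a deterministic text-preprocessing pipeline (punctuation and
    number removal, lowercasing, stop-word removal, Porter stemming),
    bag-of-words, TF-IDF and signed feature-hashing featurizers,
    chi-squared and principal-component feature reduction, uniform wrappers
    over six classical classifiers, a stratified evaluation harness with
    cross-validation and timing, and a synthetic-corpus generator with
    tunable class separability for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    ranger,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    xgboost
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
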
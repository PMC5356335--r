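Package: collboost
Title: Collaborative Subbagged Gentle Boosting for Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bi-level ensemble classifier that combines subbagging
    (stratified sampling without replacement) with Gentle Boost ensembles
    of regression stumps, and adds two inter-ensemble collaboration
    schemes based on instance exchange: weak-learner collaboration
    (W-CLB), a stochastic per-round exchange of the weakest-conviction
    correctly classified instances during boosting, and strong-learner
    collaboration (S-CLB), a post-training pairwise exchange with
    retrain-and-revert that never increases the empirical error.
    Includes margin-based instance selection, evaluation utilities
    (error rate, AUROC, stratified k-fold cross-validation, paired model
    comparison), Gaussian synthetic-data generators with closed-form
    Bayes error, JSON model persistence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
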
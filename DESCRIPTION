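Package: ifsrank
Title: Incremental Feature Selection and Rule Mining for Labeled Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies class-discriminative genes from labeled expression
    matrices (for example single-cell profiles annotated with a vaccination
    strategy per cell) by combining five feature-ranking algorithms (mRMR,
    Monte Carlo feature selection, L1-penalised one-vs-rest models,
    gradient-boosted-tree split counts, and permutation feature importance)
    with incremental feature selection under SMOTE-balanced stratified
    cross-validation. Decision-tree and random-forest classifiers are scored
    with a full multiclass metric suite (per-class F1, accuracy, multiclass
    MCC, macro and weighted F1); optimal and feasible feature subsets are
    selected from each IFS curve; interpretable if-then classification rules
    are mined from the optimal decision trees; and the five selected gene
    sets are intersected into a Venn-style consensus report. A synthetic-data
    generator with planted discriminative genes makes the whole pipeline
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
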
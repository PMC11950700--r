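Package: ddnselect
Title: Hybrid Deep-Learning-Based Feature Selection for Small Clinical
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-stage feature selection for predicting binary behavioral
    outcomes from small, mixed-type clinical cohorts. Stage 1 is a
    multimetric majority-voting filter that ranks candidate features by
    the maximal information coefficient, Gini-impurity relevance,
    information gain and a type-aware correlation score, keeps features
    selected by multiple metrics, and prunes redundant pairs by joint
    1-MIC / 1-correlation thresholds. Stage 2 is a deep dropout network
    wrapper that searches small feature subsets by cross-validated
    F1-score. The surrounding pipeline covers group-wise imputation,
    one-hot encoding, normality-guided normalization, SMOTE-NC class
    balancing, stratified splitting, downstream classifier evaluation,
    baseline filter/wrapper/embedded/hybrid selectors, a seeded synthetic
    cohort generator with planted ground truth, and radial feature
    charts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    ggplot2,
    glmnet,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
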
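Package: wolfscreen
Title: Grey Wolf Wrapper Feature Selection for Case-Control Blood-Marker Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating binary case-control classifiers on
    routine clinical laboratory panels. Includes a synthetic cohort generator
    parameterised by per-group summary statistics (means, standard deviations,
    sex and age distributions), missingness-aware and leakage-safe
    preprocessing (threshold feature elimination, fold-fitted median/mode
    imputation, z-scoring), a from-scratch binary Grey Wolf Optimization
    wrapper for feature-subset selection, five reference classifiers (random
    forest, gradient-boosted trees, RBF support vector machine, k-nearest
    neighbours, ridge logistic regression) behind a uniform interface, a
    repeated stratified k-fold cross-validation harness with confusion-matrix
    metrics and ROC/AUC, and group-comparison statistics (Welch t, Pearson
    chi-square). A command-line entry point binds the stages into reproducible
    end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    FNN,
    quadprog,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
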
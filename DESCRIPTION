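Package: hybridsample
Title: Hybrid Resampling and Ensemble Evaluation for Imbalanced Clinical Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for binary clinical classification under class imbalance:
    SMOTE over-sampling, edited-nearest-neighbour (ENN) and Tomek-link
    under-sampling, and the hybrid SMOTE-ENN and SMOTE-Tomek samplers, together
    with decision-tree ensembles (bagging, AdaBoost.M1, random forest),
    imbalance-aware evaluation (sensitivity, specificity, F-measure, Matthews
    correlation coefficient, rank-based AUC, stratified ten-fold
    cross-validation), and a nonparametric comparison protocol (paired Wilcoxon
    signed-rank tests and the Friedman test with its F transformation) for
    metric-by-algorithm result tables. Includes a seeded generator of
    imbalanced Gaussian datasets with planted noisy and boundary samples, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rpart,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
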
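Package: metabrsvd
Title: Robust Metabolomic Biomarker Identification with Missing Values and Outliers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies metabolomic biomarkers from two-group intensity matrices that
    contain both missing values and outlying cells. The core is a groupwise robust
    singular value decomposition fitted by alternating least-absolute-deviation
    regression, which simultaneously imputes missing cells and replaces cells flagged
    by the interquartile-range rule; differential metabolites are then called by a
    pooled-variance t-test with Bonferroni correction and a fold-change cut-off, and
    ranked by support-vector-machine recursive feature elimination. Includes baseline
    imputers (zero, k-nearest-neighbour, iterative random forest), an ANOVA-model
    simulation generator with controllable missingness and outlier contamination, and
    RMSE/ROC/AUC benchmarking utilities.
License: GPL (>= 3)
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
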
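Package: neurofep
Title: Global Brain Free-Energy Differences and Information-Processing
    Resources from Single-Trial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates global brain free-energy differences during
    two-alternative visual category decisions from single-trial EEG, using
    common spatial pattern (CSP) features, K-means perception indexing, and
    repeated stratified cross-validated support vector machine posteriors to
    form a recognition distribution over true stimulus categories. Couples
    the free-energy estimates to a bounded-rationality resource parameter
    (softmax inverse temperature) fitted from categorization behavior by
    intercept-free logistic regression, and provides permutation
    repeated-measures ANOVAs, max-statistic ERP/GFP tests, randomization
    correlations and Benjamini-Hochberg FDR control. Ships a full synthetic
    EEG/behavior cohort generator so every stage is testable end to end.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
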
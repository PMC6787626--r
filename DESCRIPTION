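Package: wstsev
Title: Weighted Standing Time Severity Scoring and Biomarker Analysis for ME/CFS
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing myalgic encephalomyelitis / chronic fatigue
    syndrome (ME/CFS) cohorts stratified by orthostatic-intolerance testing.
    Implements the weighted standing time (WST) severity statistic and its
    4-class and merged 3-class severity labels, POTS detection, class-median
    imputation, a nonparametric test battery (Kolmogorov-Smirnov normality
    screen, Mann-Whitney U, Kruskal-Wallis, and an exact/approximate
    Jonckheere-Terpstra trend test), a seeded random-forest severity model
    with out-of-bag evaluation and dual (Gini and permutation) importance
    rankings, CART decision trees for marker-threshold extraction, pairwise
    ROC/AUC between severity classes, and median/IQR reference intervals
    recomputed from correctly predicted cases. Includes a seeded synthetic
    cohort generator parameterised from published per-class marker summaries
    so the full pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
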
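Package: trophomode
Title: Machine-Guided Trophic Mode Inference from Protist Gene-Family Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the trophic mode (heterotrophy, mixotrophy, phototrophy) of
    marine protists from gene-family (Pfam) expression profiles. Builds labeled
    training sets from culture metadata with ordered condition-based labeling
    rules, balances classes by seeded under-sampling, selects trophic-mode
    informative gene families by a cross-validated permute-and-score
    (mean-decrease-in-accuracy) procedure over bagged and gradient-boosted tree
    ensembles, trains and evaluates multiclass classifiers (accuracy, per-class
    precision/recall, Cohen's kappa, Kruskal-Wallis/Wilcoxon/Benjamini-Hochberg
    comparisons), and deploys fitted models onto species-level environmental
    transcriptome bins with completeness, replication, and
    conflicting-prediction exclusion rules, prediction-proportion aggregation,
    diel grouping, and latitudinal trend fits. Includes a negative-binomial
    synthetic-data generator with block-structured trophic signal so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ranger,
    xgboost,
    Rtsne,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
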
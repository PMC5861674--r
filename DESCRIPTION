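Package: mirstroma
Title: Analysis of miRNA Mimic Co-Culture Screens of Fibroblast
    Pro-Tumorigenic Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing arrayed miRNA-mimic co-culture screens
    that score the pro-tumorigenic activity of lung fibroblasts, and for
    the downstream analyses such screens feed: plate-median normalization
    of two-channel cell counts and candidate hit selection; consensus
    miRNA-target integration across prediction algorithms with
    Jaccard-similarity hierarchical clustering into seed-family groups;
    percent-of-control secretome profiling of multiplex panels;
    functional-readout statistics (dual-luciferase normalization,
    four-parameter-logistic ELISA standard-curve correction,
    wound-closure half-time, linear associations); and nonparametric
    cohort statistics (median/IQR summaries, Wilcoxon comparisons,
    Spearman correlations). A synthetic-data generator with planted
    ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
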
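Package: mirforest
Title: Random-Forest Classification of miRNA Binding Sites from Duplex
    Alignment Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns mature microRNAs against candidate target mRNA
    sequences with a miRanda-style local alignment (G:U wobble aware
    scoring, empirical seed rules, score and energy thresholds), extracts
    34 structural, thermodynamic, seed and position-based features from
    each accepted duplex, and trains a random-forest classifier that
    separates true target sites from pseudo-target sites. Includes the
    full evaluation protocol: repeated stratified cross-validation,
    confusion-matrix metrics, ROC/AUC, Gini-importance ranking with
    restricted forward feature selection, label-permutation significance
    testing and partial dependence profiles, plus a synthetic generator
    of labelled miRNA/target pairs so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
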
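Package: methven
Title: Predicting Effects of Non-Coding SNPs on CpG Methylation from
    Sequence and Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implementation of the Methven framework for predicting the
    direction and magnitude (meQTL slope) of non-coding SNP effects on CpG
    methylation. Builds SNP-CpG pair datasets from meQTL tables, extracts
    CpG-centered windows from a genome with per-base ATAC-seq accessibility,
    applies a positional-wise cutting and average-pooling feature pipeline,
    and trains a dual-task stacked bidirectional GRU model (classification of
    effect direction, regression of effect slope). Includes condition
    comparison of CpG sites between case and control accessibility tracks,
    hidden-state interpretability analyses against functional-region
    annotations, and a fully seeded synthetic-data generator so that every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    rpart,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
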
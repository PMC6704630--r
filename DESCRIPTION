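Package: enetsig
Title: Two-Step Elastic-Net Classifiers and Gene Signatures for Immune
    Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains multiclass elastic-net logistic-regression classifiers
    for immune cell types and T helper subsets from labeled bulk RNA-seq
    count matrices, selecting the penalty strength by ROC/AUC against
    bootstrap-scrambled synthetic negatives, and refines the selected genes
    into per-cell-type binary gene signatures. Includes the supporting
    filtering and normalization chain (low-expression filtering, within-lane
    GC-content normalization, between-lane full-quantile normalization,
    log2 transform), missing-value augmentation with a dummy constant,
    single-cell annotation with per-specimen composition tables, PCA with a
    scrambled-data component-retention control, Fisher-exact gene-set
    benchmarking with bootstrap confidence bands, and a negative-binomial
    simulator producing labeled fixtures with planted marker genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    limma,
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
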
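Package: sumtwas
Title: Transcriptome-Wide Association Studies from Summary-Level eQTL Reference Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains per-gene cis-eQTL weight vectors from summary-level eQTL
    statistics and a linkage-disequilibrium (LD) reference panel using four
    polygenic-score-style estimators (LD clumping + p-value thresholding,
    summary-statistic LASSO with pseudovalidation, a Dirichlet-process
    normal-mixture Gibbs sampler, and a continuous-shrinkage Gibbs sampler),
    then performs gene-based TWAS association tests against GWAS summary
    statistics and combines the per-method p-values with a Cauchy-combination
    omnibus test. Includes PLINK bed/bim/fam reference-panel support, LD block
    partitioning, genomic control, valid-model and independent-gene filtering,
    and a simulation harness for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
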
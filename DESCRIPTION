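Package: qtlflank
Title: Local and Whole-Genome Bayesian Prediction of QTL Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates linkage-disequilibrium-structured SNP genotypes down
    multi-generation pedigrees, constructs heritability-one QTL phenotypes,
    and fits the Bayesian alphabet of whole-genome regression models (BayesA,
    BayesB, BayesC, BayesC0 and BayesCpi) by single-site Gibbs sampling.
    Provides pedigree additive relationship matrices, relatedness-based
    cross-validation groups, and experiment drivers that compare local
    (QTL-flanking) against whole-genome training and prediction of QTL
    genotypes across marker panel densities, flanking-window sizes,
    cross-validation folds and QTL minor allele frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
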
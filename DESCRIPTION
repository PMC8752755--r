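Package: deepnull
Title: Non-Linear Covariate Adjustment for Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a small residual-style multilayer perceptron that predicts a
    quantitative phenotype from non-genetic covariates (age, sex, batch and
    similar), produces one strictly out-of-sample prediction per individual
    through a k-partition cross-fitting scheme, and adds that prediction as an
    extra covariate in per-variant association testing. Includes a per-variant
    ordinary-least-squares association scan with Wald chi-square statistics, a
    quantitative-trait simulator with explicit variance partitioning between
    genotype, covariate functions and noise, estimator bias demonstrations, and
    GWAS evaluation utilities: power and type-I error summaries, greedy LD
    clumping of significant variants into independent hits, locus merging,
    cross-scan overlap classification, phenotype-prediction R-squared with
    bootstrap standard errors, and polygenic scores. Readers and writers for
    PLINK bed/bim/fam genotypes and whitespace-delimited phenotype/covariate
    tables are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
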
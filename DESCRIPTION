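Package: blrfine
Title: Fine-Mapping of GWAS Loci with Bayesian Linear Regression on Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical fine-mapping of genome-wide association study (GWAS)
    loci using Bayesian linear regression (BLR) models with BayesC
    (spike-and-slab) and BayesR (finite mixture) priors, fitted by Gibbs
    sampling directly on GWAS summary statistics and a linkage-disequilibrium
    (LD) correlation matrix. Includes simulators for LD-structured genotypes
    and for quantitative and binary phenotypes under tunable genetic
    architectures, single-SNP linear and logistic association scans,
    reconstruction of sufficient statistics from marginal effects and LD,
    region-wide and banded genome-wide samplers, credible-set construction
    with purity statistics, Geweke convergence diagnostics, precision / recall
    / F1 and AUC evaluation of fine-mapping output, and polygenic-score
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
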
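Package: pedmcmc
Title: Bayesian Animal Models by Gibbs Sampling, Hamiltonian Monte Carlo
    and the No-U-Turn Sampler
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the pedigree-based univariate Bayesian animal model
    y = Xb + Za + e with a | sigma2_a ~ N(0, A sigma2_a) using three
    interchangeable Markov chain Monte Carlo samplers: single-site Gibbs
    sampling, fixed-hyperparameter Hamiltonian Monte Carlo, and the
    No-U-Turn Sampler with dual-averaging step-size adaptation. Includes
    a tabular-method builder for the additive relationship matrix A and
    its Cholesky factor, a pedigree and phenotype simulator for discrete
    generations under the infinitesimal model, and MCMC quality
    diagnostics (effective sample size, lagged autocorrelation, Monte
    Carlo standard error, skewness, and breeding-value accuracy and
    unbiasedness against simulated truth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    patchwork
Config/testthat/edition: 3
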
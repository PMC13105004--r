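Package: karyotempo
Title: Tempo of Chromosome-Number Evolution on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a four-rate continuous-time Markov model of haploid
    chromosome-number change (single gains and losses, polyploidy, and
    demiploidy) on time-calibrated ultrametric phylogenies. Rates are
    estimated by Metropolis-Hastings MCMC with exponential or uniform
    priors and by maximum likelihood, with AIC-based comparison of nested
    models to assess support for polyploidy. Model adequacy is checked by
    posterior predictive simulation of chromosome-count variance and
    entropy. A cross-clade layer decomposes variance in dysploidy rates
    across taxonomic groups (one-way ANOVA, REML variance components,
    intraclass correlation, permutation tests) and regresses rates on
    covariates by phylogenetic generalized least squares. Includes
    simulators for ultrametric trees, chromosome counts under the model,
    clade-rate tables with known group structure, and Brownian covariates.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
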
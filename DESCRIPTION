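Package: swtsim
Title: Simulation and Mixed-Model Analysis of Stepped Wedge Trials with a
    Binary Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for studying bias and inference from
    misspecified mixed-effect models in stepped wedge cluster randomised
    trials. Provides a generator for cross-sectional binomial stepped wedge
    data with cluster-varying period and intervention effects, maximum
    marginal likelihood fitters for logistic mixed models with a random
    intercept and optional correlated random period or random intervention
    effects (adaptive Gauss-Hermite quadrature over one or two dimensions),
    Wald and likelihood-ratio inference, and a replication engine that
    computes percentage bias, confidence interval coverage, type I error and
    convergence rates across a grid of generative scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
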
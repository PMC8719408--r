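Package: apomap
Title: Joint Bayesian Spatio-Temporal Shared-Component Mapping of Adverse
    Pregnancy Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-area joint disease mapping for multiple adverse pregnancy
    outcomes (low birth weight, pre-term birth, stillbirth, neonatal death)
    counted against a common live-birth denominator. Implements a binomial
    logit shared-component model in which one intrinsic CAR spatial field and
    one RW1 temporal trend are common to all outcomes (scaled by per-outcome
    weights with a product-one constraint) alongside outcome-specific CAR and
    RW1 fields and an unstructured space-time interaction. Provides adjacency
    graph utilities, a synthetic space-time-cube generator with known truth,
    bivariate Poisson covariate screening, an adaptive Metropolis-within-Gibbs
    sampler with conjugate precision updates, Gelman-Rubin and Monte-Carlo
    error diagnostics, holdout posterior-predictive validation, and
    rate and percent-change reporting utilities.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
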
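Package: slcmcount
Title: Structured Latent Curve Models for Longitudinal Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits first-order multiphase structured latent curve models (SLCMs)
    to repeated-measures count data with varying exposure.  The measurement
    model is negative binomial (NB2, quadratic variance) or Poisson with a
    log link and an exposure offset whose coefficient is fixed at one; the
    structural model is a piecewise linear-linear growth trajectory with a
    freely estimated, individually varying changepoint carried into the model
    through a first-order Taylor-series (min/max) factor-loading basis.
    Time-varying NB2 dispersion parameters can be left free per occasion or
    constrained to follow a log-linear or exponential-decay-with-asymptote
    trajectory.  Estimation is by marginal maximum likelihood with adaptive
    Gauss-Hermite quadrature; cluster-robust (sandwich) standard errors,
    identification counting, empirical-Bayes trajectories, and a per-occasion
    Poisson-versus-NB2 measurement-model selection battery (empirical
    dispersion, Kullback-Leibler divergence, Pearson statistic, AIC/BIC) are
    provided, together with a synthetic-data generator emulating accelerated
    longitudinal language-sample designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
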
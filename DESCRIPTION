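Package: coarseMR
Title: Mendelian Randomisation with Coarsened Exposures
Version: 0.1.0
Authors@R:
    person("coarseMR", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Mendelian randomisation when the measured exposure is a
    coarsened (binary or ordered-categorical) proxy for a latent continuous
    trait, as in the Falconer liability-threshold model. Quantifies the
    multiplicative bias of the naive Wald/2SLS estimator in closed form,
    estimates the causal effect of a one-SD increase in the latent exposure
    via a probit or ordered-probit first stage with a liability-scale
    heritability sensitivity parameter, supports both one-sample
    (individual-level) and two-sample (GWAS summary statistics,
    inverse-variance weighted) designs, and ships a liability-threshold
    simulator for validation. Includes bootstrap inference, instrument
    pruning, GWAS summary-statistic harmonisation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
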
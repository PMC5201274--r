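Package: clpmed
Title: Cross-Lagged Panel Mediation Models for Longitudinal Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal mediation analysis with autoregressive
    cross-lagged structural equation models over multi-wave panel surveys.
    Implements questionnaire scoring and dichotomization rules for workplace
    demand/support scales (DCQ), depressive symptoms (SCL-CD6) and unhealthy
    behaviors (smoking, AUDIT/CAGE excessive drinking, diet, physical
    inactivity); latent-variable cross-lagged models with polychoric
    correlations and diagonally weighted least squares or normal-theory
    maximum likelihood (including full-information handling of missing
    cells); bivariate cross-lagged screening with a gating rule for
    mediation; product-of-coefficients total, direct and indirect effects
    over enumerated wave-spanning paths with Monte Carlo simulation
    confidence intervals; and a synthetic multi-wave cohort generator with
    known true effects for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
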
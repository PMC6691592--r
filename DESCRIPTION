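Package: bivlcs
Title: Bivariate Latent Change Score Models for Coupled Cognitive Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares structural models of coupled development in two
    cognitive domains measured at three occasions: bivariate latent change
    score (LCS) models embodying mutualism, investment, and common-factor
    accounts, plus parallel-process growth and random-intercept cross-lagged
    panel alternatives. Includes a general linear latent-variable engine with
    full-information maximum-likelihood estimation under missing data,
    equality constraints, standardized solutions and fit indices
    (RMSEA, CFI, SRMR, AIC, BIC), a model-implied-moments simulator for
    generating synthetic longitudinal datasets, and Monte-Carlo machinery for
    model-recovery and coupling-power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
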
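Package: heywoodIRT
Title: Fisher-Information Diagnostics for Heywood Cases in Item Response Theory
Version: 0.1.0
Authors@R:
    person("SAPA", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects Heywood cases (improper solutions, Guttman items) in item
    response theory models through the item Fisher information function rather
    than raw parameter values. Implements item response functions and exact
    derivatives for linear, two- to four-parameter logistic, residual
    heteroscedasticity, and nominal response models; item, category, and test
    information curves with the information-to-reliability mapping; the Item
    Fraction of Total Information (IFTI) decomposition with leverage-style
    flagging thresholds; latent-trait scoring by expected a posteriori (EAP)
    quadrature and Bartlett weighted least squares; marginal maximum likelihood
    fitting of the 2PL and residual heteroscedasticity models with optional
    Gaussian regularizing priors on the asymmetry parameter; a seeded synthetic
    response generator with planted Heywood items; and a command-line interface
    over plain-text parameter and response tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
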
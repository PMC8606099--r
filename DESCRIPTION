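Package: prodmed
Title: Product-Method Causal Mediation Analysis with Exact Binary-Outcome Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Point and interval estimation of the natural indirect effect (NIE),
    natural direct effect (NDE), total effect (TE) and mediation proportion (MP)
    via the product method, for all four combinations of continuous/binary
    outcome and mediator. For binary outcomes, provides exact expressions that
    do not rely on the rare-outcome assumption (logistic-normal integrals
    evaluated by Gauss-Hermite quadrature for a continuous mediator; exact
    enumeration for a binary mediator), alongside the classical rare-outcome
    approximation and a probit approximation. Standard errors come from
    estimating-equation sandwich covariances combined through the multivariate
    delta method; percentile bootstrap intervals are also available. A
    simulation engine generates data under calibrated effect-size targets and
    computes operating characteristics (median percent bias, coverage rates,
    variance ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
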
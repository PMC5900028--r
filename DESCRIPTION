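Package: ballberry
Title: Ball-Berry Stomatal Conductance Modelling Under Soil Water Deficit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples the Ball-Berry stomatal conductance model to leaf-surface
    humidity and CO2 through its closed-form quadratic solution, with an
    optional modification in which the Ball-Berry slope decays exponentially
    with the mean root-zone soil water potential. Provides forward prediction
    of stomatal conductance, transpiration and leaf water use efficiency from
    gas-exchange driver variables; nonlinear least-squares estimation of the
    model parameters with asymptotic confidence intervals; goodness-of-fit
    metrics and ANCOVA comparison of water-use-efficiency versus
    vapour-pressure-deficit regression lines; and synthetic greenhouse
    experiment generators (progressive pot drying; full, deficit and
    alternate partial root-zone irrigation on split-root pots) built on van
    Genuchten water retention curves, so the whole workflow is testable
    without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
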
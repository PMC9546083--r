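Package: prepostMA
Title: Meta-Analysis of Continuous Outcomes Measured at Baseline and Follow-Up
Version: 0.1.0
Authors@R:
    person("prepostMA", "Developers", email = "prepostma@example.org",
           role = c("aut", "cre"))
Description: Tools for the meta-analysis of two-arm randomised trials with a
    continuous outcome measured before and after treatment. Implements the
    three aggregate-data effect measures (follow-up scores, change scores and
    ANCOVA recovered estimates), common-effect and random-effects
    inverse-variance pooling with REML between-study heterogeneity estimation
    and the Hartung-Knapp standard-error adjustment, exact-moment pseudo
    individual participant data generation from summary statistics, and one-
    and two-stage pseudo-IPD ANCOVA models with four residual-variance
    structures and treatment-by-baseline interaction. Includes a sequential
    fill-in engine for incomplete summary data, a trial simulator for
    validation, forest and funnel plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    nlme
Config/testthat/edition: 3
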
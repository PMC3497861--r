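Package: lungtau
Title: Two-Compartment Lung Simulation and Expiratory Time Constants for
    Density-Dependent Airway Obstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quasi-steady simulation of a mechanically ventilated
    two-compartment test lung in which branch and circuit resistances follow
    the quadratic (orifice-type) pressure-loss law dP = (k/2) * rho * U^2, so
    that resistance depends on gas density and flow rate.  Supports arbitrary
    ideal-gas mixtures (e.g. dry medical air versus 78/22 helium/oxygen),
    calibration of loss-coefficient geometry from equivalent linear
    resistance tables, polynomial fitting of measured circuit pressure-flow
    curves, extraction of breath summaries from flow traces, apparent
    expiratory time constants by the Brunner fixed-point iteration, emulation
    of the ventilator-reported expiratory RC, and full factorial study sweeps
    over resistors, compliances, gases and breathing patterns.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
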
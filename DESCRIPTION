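Package: rzcycler
Title: Digital Twin for Rotary-Zone (Spatial) PCR Thermal Cyclers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a rotary-zone thermal cycler, a spatial PCR machine in
    which fixed-temperature heater blocks on a stepper-driven wheel are
    rotated sequentially into contact with a stationary sample capillary.
    Provides lumped-capacitance thermal primitives (wall resistance, lump
    capacitances, RC time constants, finite-block equilibrium temperature),
    trapezoidal stepper-motion kinematics with harness-twist-aware rotation
    planning, closed-form bounded-exponential simulation of sample
    temperature histories, a PCR protocol compiler that predicts total
    runtimes, a two-parameter exponential fitter for logged thermocouple
    traces, and reagent/duration ledgers for between-run cleaning protocols.
    Synthetic trace generation makes every component testable without
    hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
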
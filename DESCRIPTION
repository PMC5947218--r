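Package: epgx
Title: Extended Phase Graphs for Two-Compartment Systems with Exchange and
    Magnetization Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation of MRI pulse sequences for coupled two-compartment
    spin systems using extended phase graphs. Supports full Bloch-McConnell
    exchange between two pools as well as the pulsed magnetization-transfer
    formulation in which the semisolid pool carries only longitudinal states
    and is saturated directly by RF pulses through an absorption lineshape.
    Provides sequence engines for spoiled gradient echo, balanced SSFP,
    CPMG/turbo spin echo, multislice TSE with off-resonant saturation, and
    fingerprinting-style variable flip-angle trains; direct steady-state
    solvers; a brute-force isochromat oracle; NNLS T2 spectroscopy with
    myelin-water peak statistics; and constrained fitting of the
    magnetization-transfer model to transient signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
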
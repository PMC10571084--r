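Package: magsense
Title: Equilibrium Speciation and Ratiometric Calibration for Fluorescent Magnesium Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for ratiometric fluorescent metal-ion
    indicators, built around a quinoline-dicarboxylate Mg(2+) sensor.
    Provides a multi-component chemical equilibrium speciation solver
    (sensor, H+, Mg2+, Ca2+, Zn2+, ATP and ternary sensor-metal-nucleotide
    complexes), a Gaussian-band emission model that composes speciation
    states into two-channel fluorescence ratios, nonlinear least-squares
    estimation of apparent dissociation constants, pKa and ternary-complex
    constants from titration data, selectivity panels, per-cell ratio
    statistics for imaging and flow-cytometry populations, and synthetic
    data generators with ground-truth sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
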
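Package: dsfsim
Title: Simulation and Analysis of Microcontroller-Based Differential
    Scanning Fluorimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pure-software counterpart to a low-cost, microcontroller-
    controlled differential scanning fluorimetry (DSF) instrument. Provides a
    discrete-time simulator of the heating hardware (NTC thermistor
    conversion, sensor averaging, PID duty-cycle control of a first-order
    heat-pad plant, and the step-wise heat/incubate/measure schedule), a
    synthetic plate-run generator with dye-specific fluorescence models
    (SYPRO Orange, CPM, ThermoFAD) including blanks, post-denaturation decay,
    air-exposure amplitude loss and detergent-probe interference, and the
    melting-curve analysis pipeline: blank subtraction, replicate averaging,
    truncation of post-denaturation data, Boltzmann and double-Boltzmann
    sigmoid fitting with second-derivative fallback, pad-to-well temperature
    calibration, and delta-Tm buffer/detergent screening reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
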
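Package: gripsim
Title: Closed-Loop Precision-Grip Simulation with Risk-Sensitive Basal
    Ganglia Action Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates precision grip-and-lift trials with a stick-slip
    two-body plant, an underdamped second-order grip-force controller and
    a PID lift-force controller, and models trial-to-trial grip-force
    selection as risk-sensitive action selection in the basal ganglia.
    Value and risk surfaces over the grip-force reference are estimated
    by Monte Carlo over noisy lifts and smoothed by radial-basis-function
    regression; a Go/Explore/NoGo stochastic hill-climbing rule driven by
    the utility-gradient dopamine signal selects grip forces, with
    dopamine-range clamping to emulate Parkinson's disease ON and OFF
    medication states. Includes genetic-algorithm calibration of
    controller and selection parameters and drivers that reproduce the
    grip-force statistics of classic patient studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
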
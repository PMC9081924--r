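Package: phcvad
Title: Physiological Speed Control for Centrifugal Ventricular Assist Devices
Version: 0.1.0
Authors@R:
    person("phcvad", "maintainers", email = "maintainers@phcvad.dev", role = c("aut", "cre"))
Description: Sensorless modular physiological speed control for a centrifugal
    left ventricular assist device (LVAD), together with the pump-signal
    estimators it depends on (heart rate, flow pulsatility, suction events,
    aortic valve opening) and a closed-loop lumped-parameter cardiovascular
    testbench. The testbench reproduces orthostatic transitions, the Valsalva
    maneuver and ramped submaximal ergometry in silico so the controller can
    be exercised and validated without clinical data. Includes phase
    segmentation and crossover-style comparison of constant-speed versus
    physiologically controlled runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
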
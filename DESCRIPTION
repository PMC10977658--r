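Package: otsforce
Title: Force Analysis for DNA Overstretching Tension Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for DNA overstretching tension
    sensor (OTS) experiments: optical-tweezers dehybridization-force
    calibration (kymograph changepoint detection, Gaussian force-distribution
    fits, freely-jointed-chain loading-rate conversion, Bell-Evans trend
    fits), single-molecule fluorescence image analytics (spot detection,
    unit-intensity calibration, molecule counting, frame-difference maps,
    track linking, censored lifetime fits), and two-level serial-sensor
    loading-rate estimation from two-channel activation delays (greedy
    colocalization, interval-censored exponential maximum likelihood with
    bootstrap confidence intervals). A synthetic-data generator emulates
    every input so the full chain is verifiable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
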
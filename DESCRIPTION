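Package: emgsentry
Title: Fault-Tolerant Surface EMG Movement Classification with Virtual Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for fault-tolerant myoelectric
    movement classification. Generates multichannel surface electromyography
    (sEMG) recordings following a 12-electrode, 17-movement acquisition
    protocol; simulates the five canonical sEMG contaminants (motion
    artifact, electrode displacement, amplifier saturation, power-line and
    ECG interference); detects degraded channels online with a two-class
    support-vector detector and temporal activation logic; reconstructs
    degraded channels with a virtual sensor driven by multichannel
    cross-correlation, using either a time-varying ARMA model with
    basis-expanded coefficients or a steady-state Kalman estimator; and
    quantifies accuracy recovery across seven classification settings with a
    three-factor analysis of variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
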
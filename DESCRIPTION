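Package: icgdx
Title: Simulation and Convolutional Classification of Multi-Sensor
    Impedance Cardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, fully reproducible pipeline for detecting
    aortic dissection in synthetic impedance cardiography (ICG) signals.
    Provides a documented surrogate waveform generator for virtual-patient
    cohorts (3 injector electrode pairs x 5 sensor pairs x 20 time steps
    over half a cardiac cycle, parameterised by true-lumen radius,
    hematocrit, false-lumen radius and false-lumen angle, with additive
    Gaussian noise), a branch-fusion one-dimensional convolutional
    classifier with reference softmax and cross-entropy operations, a
    deterministic SGD-with-Nesterov-momentum training loop with early
    stopping, and evaluation tools: accuracy, sensitivity and specificity
    with replication spread, and accuracy sweeps over false-lumen radius
    and noise level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
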
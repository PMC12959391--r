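Package: stretchsuit
Title: Digital Twin of a Full-Body Strain-Sensing Textile Suit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale digital twin of a full-body garment instrumented with
    capacitive textile stretch sensors. Builds a procedural articulated body with
    a skinned triangle mesh, optimizes sensor placements by geodesic skin-stretch
    over joint sweeps, forward-simulates 38-channel capacitance streams with
    parasitics, spatially propagating drift and noise, generates labeled synthetic
    motion protocols (single-joint sweeps, calisthenics-like routines, periodic
    reaches, treadmill gait), and implements the full calibration and
    pattern-recognition pipeline: stream resampling and squat-peak
    synchronization, a multilayer-perceptron joint-angle regressor, a
    Savitzky-Golay drift baseline, frequency-domain motion profiling, and an LSTM
    gait/reach classifier.
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
    igraph,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
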
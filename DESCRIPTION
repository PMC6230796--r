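Package: contrastgain
Title: Contrast Gain Control Analysis for Laminar Auditory Cortex Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying contrast gain control in auditory cortex
    from multichannel extracellular recordings. Generates dynamic random
    chord (DRC) stimuli with parametric contrast, extracts analog multiunit
    activity and local field potentials from raw voltage traces, fits
    separable spectrotemporal receptive fields (STRFs) by alternating least
    squares with a sigmoidal output nonlinearity whose threshold and gain
    may differ between contrast conditions, assigns cortical layers by
    inverse current source density analysis, and runs the population and
    laminar statistics. A synthetic-data generator with known ground truth
    (linear-nonlinear model units, raw voltage with spike wavelets, laminar
    potentials from a known current source density) makes every stage
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    emmeans,
    car,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
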
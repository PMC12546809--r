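Package: neurotrainr
Title: Closed-Loop Simulation of Multimodal Neurofeedback Cognitive Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully synthetic, desk-scale simulator of a multimodal
    neurofeedback system for collaborative training of executive function
    and tactical cognition. Generates band-structured EEG and auxiliary
    physiological streams with controlled signal-to-noise ratio, extracts
    spectral, phase-locking, cross-frequency-coupling and hemodynamic
    markers, fuses modalities with a scalar Kalman filter, evolves
    session-level cognitive-state dynamics under BCM-style plasticity and
    adaptive difficulty control, and evaluates simulated cohorts with
    repeated-measures statistics and effect sizes. All results are tidy
    tibbles designed for pipe-based workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
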
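Package: gazesweep
Title: Gaze-Based Analysis of Visual Search Efficiency in Room-Clearance Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing head-mounted eye-tracker
    recordings from simulated room-clearance (close-quarter battle) search
    tasks. Implements zero-phase Butterworth preprocessing of 120 Hz angular
    gaze traces, dispersion-based (I-DT) fixation detection, adaptive
    acceleration-threshold saccade detection, and a battery of scanpath
    efficiency metrics: gaze transition entropy over room-segment areas of
    interest, saccadic and intersaccadic angles with persistent/antipersistent
    classification, search rate, time to fixate the first target, and search
    order compliance. Includes a seeded synthetic-data generator producing
    ground-truth-labelled gaze recordings and multi-participant pre/post
    training study designs, and a group-by-time mixed ANCOVA stage with
    covariate retention and Holm-corrected post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    signal,
    pracma,
    stats,
    jsonlite,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
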
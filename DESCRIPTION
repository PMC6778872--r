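Package: physioevents
Title: Detect Individually Salient Moments in Wearable Autonomic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes three-channel wearable recordings of autonomic
    nervous system activity (electrodermal activity, fingertip skin
    temperature, and heart rate, nominally sampled at 15 Hz) to flag
    moments of heightened physiological salience. Provides an artifact
    repair and downsampling chain with modality-specific smoothing (a
    one-Euro filter for electrodermal activity, exponential decay for
    temperature, a cubic smoothing spline for heart rate), a rule-based
    signal-quality index with session-level validity masking, weighted
    multi-modal event detection from electrodermal reactions,
    temperature trend excursions, and heart-rate peak prominence, and a
    deterministic grid-search tailoring loop that fits per-individual
    detector parameters from annotated sessions and from true/false
    positive feedback on detected events. A synthetic-session generator
    with known embedded events supports fully self-contained testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
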
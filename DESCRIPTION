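Package: affectr
Title: Affective State Recognition from Wearable Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising momentary affective states
    from multi-day wrist-worn physiological recordings (1 Hz heart rate,
    40 Hz galvanic skin response, 20 Hz tri-axial acceleration) paired with
    experience-sampling (ESM) self reports. Provides readers for per-subject
    sensor and questionnaire tables; a preprocessing chain (acceleration
    magnitude, decimation to 1 Hz, least-mean-squares adaptive noise
    cancellation, moving median smoothing, 30-minute pre-prompt window
    extraction); PANAS, valence and arousal label derivation; a
    Transformer-encoder classifier with per-modality convolutional feature
    extraction and concatenation fusion, implemented with exact analytic
    gradients; subject-separated training and evaluation with Adam, linear
    learning-rate decay and early stopping; modality-ablation and
    hyperparameter-grid runners; and a synthetic-data generator that emulates
    the recording structure with controllable class-dependent effects so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
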
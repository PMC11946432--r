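Package: roadhypnosis
Title: Multimodal Identification of Road Hypnosis with a Hybrid
    Boosted-Tree Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for identifying road hypnosis (driving without
    awareness) from synchronized EEG, eye-tracking and vehicle telemetry.
    Provides modality-specific feature extractors (Welch band power with a
    brick-wall FFT bandpass, windowed-sinc FIR filtering with locally
    linear embedding for eye movements, sliding-window vehicle
    kinematics), feature standardization and time-grid fusion, a hidden
    Markov decoder whose per-state emission likelihoods come from
    Platt-calibrated gradient-boosted trees, a linear hypnosis-degree
    readout, grouped cross-validation metrics, model interpretation
    (split importance, additive attribution, local surrogates, L1
    selection, recursive elimination), and a synthetic multimodal
    recording generator with latent-state ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
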
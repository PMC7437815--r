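Package: ripplescreen
Title: Sharp-Wave Ripple Features as Predictors of Spatial Memory Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking hippocampal sharp-wave ripple (SWR)
    features measured at rest to later spatial-memory performance. Provides
    LFP preprocessing (zero-phase band-pass filtering, anti-aliased
    downsampling, velocity-based immobility segmentation), Hilbert-envelope
    SWR detection with baseline-SD thresholding, multitaper SWR-triggered
    spectrograms and z-scored slow-gamma (30-50 Hz) power, Morris water maze
    and active place avoidance behavioral metrics, composite z-scored
    performance scores, cross-cohort linear prediction with leave-one-out
    robustness checks, and a seed-deterministic synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
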
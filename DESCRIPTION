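Package: apneafusion
Title: Explainable ECG and SpO2 Fusion Models for Sleep Apnea Event Detection
Version: 0.1.0
Authors@R: person("Apnea", "Fusion Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A CPU-scale, fully tested pipeline for minute- and event-level sleep
    apnea detection from paired electrocardiogram (ECG) and pulse-oximetry (SpO2)
    recordings. Provides a synthetic signal generator with programmed apnea events
    (RR-interval modulation in ECG, lagged oxygen desaturations in SpO2, both
    clinical annotation dialects, artifact bursts), overlapping-window
    segmentation, Butterworth bandpass preprocessing, autocorrelation-graph
    signal-quality screening, two fixed one-dimensional convolutional network
    branches with feature-level fusion and selective dropout for mismatched
    sampling rates, an additive white Gaussian noise robustness protocol, and
    one-dimensional Grad-CAM heatmaps with banded importance quantization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
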
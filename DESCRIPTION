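Package: ecgcsl
Title: Cost-Sensitive Deep Learning for Imbalanced ECG Heartbeat Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for AAMI five-class heartbeat
    classification from single-lead ambulatory ECG under extreme class
    imbalance. Provides dual median-filter baseline-wander removal and
    low-pass FIR denoising, Pan-Tompkins R-peak detection, T-to-T beat
    segmentation into fixed 400-sample feature vectors, a one-dimensional
    convolutional network with multi-kernel temporal transition modules, a
    per-batch dynamic cost-sensitive loss that blends batch and dataset
    class weights with a false-positive/false-negative-rate harmonic-mean
    penalty, and the intra-patient (10-fold) and inter-patient (DS1/DS2)
    evaluation protocols with per-class, macro and aggregate metrics. A
    deterministic synthetic-ECG generator with controllable class imbalance
    makes the whole pipeline testable without access to clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
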
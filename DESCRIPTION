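Package: striatophot
Title: Fiber Photometry Normalization and Locomotion-Coupled Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel fiber photometry recordings of
    striatal projection neurons and dopamine sensors. Implements sliding-percentile
    dF/F0 normalization with isosbestic (405 nm) RANSAC affine referencing and
    quality-control gating for GCaMP recordings, a raw-channel referencing chain for
    red dopamine sensor recordings under optogenetic stimulation, rotary-encoder
    velocity calibration, threshold-based locomotion bout segmentation (treadmill
    movement/rest, open-field ambulation and immobility), peri-event alignment with
    activity-timing and offset-slope statistics, stimulation-locked dopamine
    amplitude metrics, and a small statistics/reporting layer. A synthetic session
    generator with recorded ground truth (photobleaching, shared motion artifacts,
    locomotion-coupled calcium transients, stimulation-locked dopamine dynamics)
    makes the whole chain testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
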
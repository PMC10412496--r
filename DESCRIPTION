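Package: gaitbouts
Title: Walking-Bout Detection from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects walking bouts and stride/step events from 3-axis
    gyroscope or accelerometer signals recorded at the foot. The raw
    signal norm is peak-enhanced (downsampling, zero-phase FIR low-pass
    filtering, single-scale continuous wavelet transform with a
    second-derivative-of-Gaussian kernel, Savitzky-Golay smoothing),
    stride- or step-related peaks are selected with fixed, adaptive
    (percentile) or Hilbert-envelope thresholds, and selected events are
    grouped into walking bouts with an adaptive inter-event duration
    threshold for single- and dual-sensor configurations. Includes
    per-sample confusion metrics and percentile ROC sweeps for
    validation against reference locomotion labels, and a synthetic
    gait-signal simulator with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
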
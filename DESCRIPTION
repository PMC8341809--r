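Package: uluse
Title: Sensor-Based Assessment of Upper-Limb Use, Intensity, and Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and measures for quantifying upper-limb functioning
    from wrist-worn inertial sensors in neurorehabilitation. Implements binary
    use signals, gated instantaneous intensity, and their causal windowed
    averages (average use, average intensity, average activity); concrete use
    and intensity detectors (activity counts with thresholding, and a
    gross-movement score based on forearm orientation); the percentile-based
    summary measures Hq (overall activity) and Rq (relative bilateral use with
    preferred-limb sign); laterality visualization geometries (use-intensity,
    bilateral-magnitude vs magnitude-ratio, left-right intensity, and
    intensity sum-difference planes) with L1-L4 reference curve families; a
    functional workspace density estimator; and a synthetic-data module that
    generates scenario point clouds, laterality patterns, and full two-limb
    IMU epochs with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
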
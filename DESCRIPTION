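Package: bitewatch
Title: Multimodal Eating-Event Detection from Wrist, Jaw, and Breathing Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for recognising eating events (hand-to-mouth gestures,
    chewing, and swallowing) from three wearable sensing modalities: a wrist
    inertial unit (3-axis accelerometer + 3-axis gyroscope), a jaw-mounted
    piezoelectric film, and a two-belt respiratory inductance plethysmograph
    (RIP). Provides a synthetic session generator emulating a scripted
    eating/non-eating protocol, zero-phase filtering and per-modality signal
    formats, fixed-duration windowing and breathing-cycle segmentation with
    shape normalisation, per-window feature registries, cross-sensor feature
    vector fusion by nearest window midpoints with past/future context, and
    per-measure support vector machine classification with PCA reduction and
    micro-averaged F1 evaluation over sensor-combination by context-size grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
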
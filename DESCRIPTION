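Package: breathdetect
Title: Detection and Classification of Breathing Patterns from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and evaluating per-second breathing-event
    detectors from chest- and abdomen-worn inertial sensor signals. Includes a
    seeded simulator of 12-channel accelerometer/gyroscope breathing recordings
    (normal breathing, central and obstructive apnea, cough, sigh, yawn), a
    dataset builder that injects labeled event clips into 30-second segments of
    normal breathing with boundary smoothing and per-second labels, a
    self-contained 1D convolutional network engine (AlexNet-style window
    classifiers and a residual per-second detector) with seeded training, and an
    evaluation suite (per-class precision/recall/F1, confusion matrices, ROC/AUC,
    detection-lag analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
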
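Package: motionprint
Title: Per-User Motion-Sensor Biometrics for Shared Tablet Use Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying a target child user of a shared tablet from
    inertial motion-sensor streams. Provides a seeded synthetic cohort
    generator that emulates SensorLog-style 100 Hz accelerometer and gyroscope
    recordings of a two-part sedentary protocol (laying, then sitting), with
    per-user micro-movement signatures, position-dependent device orientation
    and slow within-session attitude drift; windowed feature engineering (a
    56-statistic feature vector per non-overlapping 1-second window);
    one-vs-rest per-user authentication models (k-nearest neighbours, random
    forest, a feed-forward neural network, and a compact dual-stream
    temporal/frequency transformer over raw windows); experiment builders for
    decoy (unseen-negative) evaluation and training-data length, time
    proximity and user-position sweeps; and median/IQR metric reporting
    across targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    ggplot2,
    jsonlite,
    pracma,
    ranger,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
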
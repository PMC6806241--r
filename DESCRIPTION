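Package: quathar
Title: Quaternion-Based Human Activity and Posture Recognition from
    Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates labeled 9-axis inertial/magnetic (IMMU) recordings for
    scripted activity protocols, estimates body attitude with a gradient-descent
    sensor-fusion filter (Madgwick-type), classifies per-sample feature vectors
    with a random-subspace KNN ensemble, and evaluates recognition with
    leave-one-subject-out cross-validation and per-class confusion-matrix
    metrics.  Supports comparison of raw accelerometer/gyroscope features
    against norm, Euler-angle and quaternion attitude features for recognition
    of static postures and dynamic activities such as stair ascent and descent.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
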
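Package: copgait
Title: Center-of-Pressure Trajectory Prediction from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the stance-phase center-of-pressure (COP)
    trajectory of human gait from body-worn inertial measurement units (IMUs).
    Provides a calibrated synthetic gait simulator (coupled IMU, vertical
    ground reaction force and COP streams), threshold-based gait-event
    detection, stream synchronization from a stomp artifact, many-to-one
    sliding-window dataset construction, a three-layer LSTM sequence
    regressor trained with RMSprop (implemented in single-precision
    'RcppArmadillo'), NRMSE and area-based Jaccard curve-similarity metrics,
    and a sensor-placement combination sweep over all subsets of the heel,
    lateral, toe and waist sites.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
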
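Package: gaitfuse
Title: Fusion of Impulse-Radar and Depth-Sensor Position Tracks for Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for indoor monitoring of walking persons with impulse-radar
    and depth (Kinect-class) sensors. Provides a synthetic trajectory and
    sensor-track simulator (red-noise radar model, ellipse-silhouette depth
    model with occlusion), three track-fusion methods (a nearly-constant-
    velocity Kalman filter, a multilayer perceptron, and a NARX recurrent
    network trained on synthetic data), extraction of healthcare-related gait
    parameters (motion intervals, turns, travelled distance, mean walking
    speed), and empirical-CDF uncertainty indicators for position and
    parameter estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
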
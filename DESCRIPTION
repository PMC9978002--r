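Package: graspsense
Title: Grasped-Object Stiffness Recognition for Under-Sensorized Prosthetic Hands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop toolkit for recognizing the stiffness of a grasped
    object from the intrinsic sensing of a single-motor under-actuated
    prosthetic hand (motor-side current, reference position, encoder
    position), with no dedicated force sensors. Provides a physics-based
    grasp-trace simulator (cascade PD position / PI current control of a
    DC-motor drivetrain closing on spring-like objects), a protocol-driven
    labeled-dataset builder, a One-vs-All non-linear logistic regression
    classifier with validation-tuned decision thresholds, vibrotactile
    feedback encodings with method-of-limits amplitude calibration, and an
    F1-score evaluation harness that runs simulated closed-loop sessions
    under four feedback conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
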
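Package: gaitmos
Title: Gait Monitoring, Margin of Stability and Robot-Guided Walking Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing overground walking recorded with
    sensorised insoles (force-sensitive resistors plus an inertial
    measurement unit per foot) and a mobile guide robot carrying a
    depth camera. Detects heel-strike and toe-off events from insole
    load, fuses foot-mounted IMU data with camera pose fixes in an
    error-state extended Kalman filter (with zero-velocity updates
    during foot-flat) to estimate stride length, stride velocity and
    step width, computes the dynamic margin of stability from the
    extrapolated centre of mass and the base-of-support convex hull,
    simulates the robot's PI distance-keeping control loop on an oval
    walking track, and provides dual-task cohort statistics
    (means/CVs, contrasts, hierarchical regression with delta
    R-squared, and detectable-effect-size power analysis). A synthetic
    walking-data generator with ground-truth kinematics makes every
    stage testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
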
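Package: beeland
Title: Sensorimotor Control Analysis of Bumblebee Landing Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse visually guided landing manoeuvres of flying
    insects from 3-D trajectory recordings. Computes optical-expansion state
    variables (distance, approach velocity and acceleration, relative rate of
    expansion r = V/y), detects constant-r set-point segments and the
    transient entry segments preceding them, identifies the closed-loop
    sensorimotor dynamics by transfer-function fitting of the step response,
    characterises transients as motion at constant expansion-acceleration,
    and fits gamma and linear mixed-effects models to the resulting
    kinematic parameters. Includes a closed-loop landing simulator that
    generates synthetic cohorts with ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    fitdistrplus,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
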
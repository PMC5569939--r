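Package: palsy3d
Title: 3D Morphable Face Models from 2D Landmarks for Facial-Palsy
    Rehabilitation Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a linear 3D morphable face model (mean shape plus identity
    and expression principal axes) to sparse 2D facial landmarks under a
    weak-perspective camera, by alternating closed-form scaled-orthographic
    pose estimation and ridge least-squares coefficient updates. Ships
    iBUG-style 68-point landmark I/O, a hybrid merge of two landmark
    fitters' outputs, ocular-scaled landmark error evaluation, region-based
    facial-motion statistics and rehabilitation progress measures for
    asymmetric conditions such as facial palsy, and a synthetic generator
    of morphable models, patient cohorts and noisy landmark observations
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
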
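Package: nanolock
Title: Closed-Loop Sample Stabilization Simulation for Super-Resolution
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Build, exercise and verify an active three-dimensional
    sample-stabilization loop of the kind required by MINFLUX- and
    RASTMIN-type nanoscopy: lateral locking from sub-pixel 2D Gaussian
    fits of fiducial markers, focus locking from the lateral shift of a
    totally internally reflected beam tracked by center of mass, and PI
    feedback driving a quantized open-loop piezo stage. A virtual
    microscope renders shot-noise camera frames under a ground-truth
    drift model behind the same camera/stage proxy contracts used for
    real hardware, so the full closed loop can be validated to
    sub-nanometer residuals without any hardware. Includes calibration
    of the camera pixel size and of the axial response against commanded
    stage motion, Gaussian-fit precision summaries of displacement
    traces, and reproducible simulation experiments driven by a
    serializable session configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    parallel,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
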
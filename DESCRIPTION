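Package: motorcargo
Title: Two-Channel Particle Tracking and Motor-on-Cargo Geometry for
    Intracellular Vesicle Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-colour single-particle imaging of
    motor-driven vesicle transport: simulation of ground-truthed vesicle and
    motor-channel detections with chromatic aberration, sub-pixel spot
    localization by 2D Gaussian fitting, channel registration (affine plus a
    smooth residual field), frame-wise two-channel colocalization pairing,
    nearest-neighbour track linking with gap closing, segmentation of
    trajectories into directional runs by velocity-direction correlation,
    motor-cargo projected-distance and angle statistics with opposite-run
    (reversal) analysis, and one- versus two-component Gaussian modelling of
    run-speed distributions compared by the extra sum-of-squares F test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    mgcv,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
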
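Package: projalign
Title: Projection-Based Automatic Sample Alignment with a Virtual Tomography Beamline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic alignment of approximately cylindrical specimens from X-ray
    projection images, together with a fully virtual beamline for testing the
    algorithms without hardware. Provides a Beer-Lambert projection simulator for
    mounted cylindrical phantoms (with edge-enhancement fringes, detector noise and
    saturation), a motorized-stage model with rotation-aware motor commands and a
    two-axis goniometer pivoting at the sample base, threshold segmentation with
    row cleaning, per-row center-of-mass statistics and axis fitting, pixel-size
    calibration by subpixel cross-correlation, closed-loop feedback alignment at
    0 and 90 degrees, specimen length measurement and fractional-length region-of-
    interest placement, and a scripted batch sequencer with a repeat-loading
    precision harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
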
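Package: ivdcalib
Title: Multi-Response Surface Calibration of Lumbar Intervertebral Disc
    Finite-Element Material Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrates the eleven material parameters of a human lumbar
    intervertebral disc finite-element model against experimental stiffness
    and bulge measurements from six standard mechanical tests, using
    multi-response surface methodology. Provides two-level fractional
    factorial design generation over the coded parameter space, a virtual
    disc responder (a reference bundle of affine response surfaces standing
    in for the finite-element solver), ordinary least-squares surrogate
    fitting with p-value-based term selection and ANOVA reporting,
    Derringer-Harrington desirability optimization under three adjustment
    criteria, and normalized mean-absolute-error validation against the
    experimental targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
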
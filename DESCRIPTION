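Package: aptkit
Title: Assessment of CBCT-Based Adaptive Proton Therapy on Digital Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for evaluating cone-beam CT (CBCT) driven
    adaptive intensity-modulated proton therapy (IMPT) workflows without
    patient data. Generates seedable digital head-and-neck phantoms with
    weekly anatomical change and degraded CBCT renditions; performs B-spline
    deformable image registration, synthetic-CT construction and contour
    propagation; computes spot-scanning proton dose with an analytic
    pencil-beam engine; optimizes robust IMPT spot weights over setup and
    range uncertainty scenarios with weekly re-planning; and quantifies
    outcomes via DVH indices, 3D gamma analysis, Dice coefficients,
    inverse-DVF dose accumulation, Lyman-Kutcher-Burman NTCP models and
    paired statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
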
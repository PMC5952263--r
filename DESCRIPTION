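Package: corddose
Title: Spinal-Cord Contour Propagation and Delivered-Dose Accumulation for
    Image-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates manually drawn spinal-cord contours from kilovoltage
    planning CT scans to daily megavoltage guidance CT scans using
    intensity-based deformable image registration (gradient-ascent
    maximisation of mutual information over translation, rigid, affine and
    cubic B-spline free-form transforms), evaluates the propagated contours
    slice by slice with a conformity suite (Jaccard conformity index,
    distance between centres, distance to conformity, left-right and
    anterior-posterior dimension differences), and accumulates per-fraction
    delivered dose to cord voxels through the recovered transforms,
    reporting dose-volume statistics including the near-maximum dose D2%.
    Includes readers and writers for DICOM CT series, RTSTRUCT and RTDOSE
    objects and NIfTI-1 volumes, and a synthetic neck phantom generator
    with ground-truth deformations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
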
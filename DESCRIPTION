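Package: limbalign
Title: Weight-Bearing Lower-Limb Alignment from Biplanar Radiographs via
    2D-3D Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers non-weight-bearing CT bone volumes to biplanar
    standing radiographs acquired with a calibrated slot-scanning
    (EOS-style) system, using intensity-based 2D-3D rigid registration
    with digitally reconstructed radiographs, a variance-weighted
    localized normalized cross-correlation similarity and derivative-free
    BOBYQA pose optimization.  Transforms 3D bone surface models into the
    weight-bearing pose and measures the mechanical axis (MA) and joint
    line convergence angle (JLCA) in 3D.  Includes fiducial-based
    validation machinery (marker extraction, stereo triangulation, rigid
    point-set fitting, error-matrix decomposition) and a parametric
    synthetic leg phantom with known ground truth so the whole pipeline
    can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minqa,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
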
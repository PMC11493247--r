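Package: curvecage
Title: Curve-Constrained Cage-Based Template Deformation for 4D Segmentation
Version: 0.1.0
Authors@R:
    person("Curvecage", "Developers", email = "curvecage@example.org",
           role = c("aut", "cre"))
Description: Segments organs from spatiotemporal (4D) volume sequences by
    deforming a watertight triangle-mesh template bound to a free-form
    deformation cage through harmonic coordinates.  Planar constraint curves
    (kappa-curve splines through user control points on axis-aligned
    cross-sections) are resampled at equal arc-length intervals and fitted by
    alternating closest-point association with a Laplacian-regularized
    quadratic cage optimization, frame by frame.  Curves shared across frames
    are linearly interpolated in time between keyframes.  Includes a synthetic
    phantom generator, mesh/label-volume export (OBJ, PLY, NIfTI) and a batch
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    rlang,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
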
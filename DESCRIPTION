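Package: warpreg
Title: B-Spline Image Registration with a Symmetric Jacobian
    Singular-Value Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-deformation nonlinear registration of 3D volumes using a
    cubic B-spline free-form deformation, a mean-squares similarity term and
    the SPRED regulariser: a symmetric lognormal prior on the singular values
    of the local Jacobian of the transformation, penalising expansions and
    contractions equally and diverging as the deformation approaches folding.
    Provides analytic gradients and sparse Gauss-Newton Hessians for the
    penalty and similarity terms, a Levenberg-damped optimiser with a
    diffeomorphism guard and a multi-resolution pyramid, Jacobian-determinant
    and cube-volume-aspect-ratio warp-quality metrics, label overlap scores,
    and a synthetic phantom generator with ground-truth diffeomorphic warps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    graphics,
    grDevices,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
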
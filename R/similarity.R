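#' Mean-squares image dissimilarity
#'
#' Mean over in-mask voxels of `(f - g)^2` for two volumes on the same grid.
#' This is the user-facing similarity metric; the optimiser works with the
#' sum form (see [msq_grad_hessian()]) so that a single trade-off weight
#' `lambda` balances similarity against regularisation.
#'
#' @param ref,warped [image_volume()]s on identical geometry.
#' @param mask optional logical/0-1 array restricting the domain.
#' @return scalar mean squared intensity difference.
#' @export
msq_value <- function(ref, warped, mask = NULL) {
  if (!same_geometry(ref, warped))
    stop("msq_value: geometry mismatch between images")
  d2 <- (ref$data - warped$data)^2
  if (is.null(mask)) mean(d2) else mean(d2[as.logical(mask)])
}

#' Similarity term with Gauss-Newton derivatives
#'
#' Volume-weighted sum-of-squares data term `0.5 * v * sum_n r_n^2` with
#' `r_n = f_n - g(t(x_n))` and `v` the voxel volume of the sample grid
#' (mm^3). Weighting by `v` makes the term a Riemann sum of the squared
#' residual, so it is commensurate with the volume-weighted regularisers
#' and the trade-off weight `lambda` keeps its meaning across pyramid
#' levels of different sampling density.
#'
#' The term is differentiated analytically with respect to the warp
#' coefficients:
#' the moving image is modelled as an interpolating cubic B-spline, so its
#' spatial gradient at the warped sample positions is the derivative of that
#' interpolant. The Gauss-Newton Hessian is `J_r' J_r` with the same
#' support-overlap sparsity as the regulariser Hessian. Samples falling
#' outside the moving volume contribute zero residual and zero derivative.
#'
#' @param ref reference [image_volume()] (defines the sample grid).
#' @param moving moving [image_volume()].
#' @param warp current [spline_warp()].
#' @param mask optional logical/0-1 array on the reference grid.
#' @param derivatives `"none"`, `"gradient"` or `"hessian"`.
#' @param cache internal per-level cache (prefiltered moving image and
#'   Kronecker bases); leave `NULL` normally.
#' @return `penalty_result` with `value = 0.5 sum r^2`, densities
#'   `0.5 r_n^2`, gradient and sparse GN Hessian.
#' @export
msq_grad_hessian <- function(ref, moving, warp, mask = NULL,
                             derivatives = c("hessian", "gradient", "none"),
                             cache = NULL) {
  derivatives <- match.arg(derivatives)
  geom <- geometry_of(ref)
  if (is.null(cache))
    cache <- list(mov_coefs = bspline_prefilter(moving$data),
                  kb = if (derivatives != "none")
                         warp_kron_bases(warp, geom, derivs = FALSE))
  vox <- warped_voxel_coords(moving, warp, geom)
  s <- sample_volume_coefs(cache$mov_coefs, vox, fill = 0,
                           gradient = derivatives != "none")
  r <- as.vector(ref$data) - s$value
  w <- if (is.null(mask)) rep(TRUE, length(r)) else as.logical(mask)
  w <- w & s$infield         # out-of-field samples carry no information
  r[!w] <- 0
  v <- voxel_volume(geom)
  dens <- 0.5 * v * r^2
  grad <- NULL; H <- NULL
  if (derivatives != "none") {
    gmm <- s$grad / rep(moving$voxel_size, each = nrow(s$grad)) # per mm
    gmm[!w, ] <- 0
    M <- n_coef(warp)
    K0 <- cache$kb$K0
    grad <- numeric(3L * M)
    for (i in 1:3)
      grad[((i - 1) * M + 1):(i * M)] <-
        as.numeric(Matrix::crossprod(K0, -v * r * gmm[, i]))
    if (derivatives == "hessian") {
      Gs <- do.call(cbind, lapply(1:3, function(i) -gmm[, i] * K0))
      H <- v * Matrix::crossprod(Gs[w, , drop = FALSE])
      H <- methods::as(Matrix::forceSymmetric(H), "CsparseMatrix")
    }
  }
  structure(list(value = sum(dens), densities = array(dens, geom$shape),
                 gradient = grad, hessian = H, type = "msq", geom = geom,
                 v = voxel_volume(geom), min_det = NA_real_, finite = TRUE,
                 n_infield = sum(w)),
            class = "penalty_result")
}
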
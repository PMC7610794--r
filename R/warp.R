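#' Cubic B-spline free-form deformation
#'
#' A `spline_warp` represents the transformation `t(x) = x + d(x)` where each
#' component of the displacement `d` (in mm) is a uniformly spaced 3D cubic
#' B-spline expansion. The knot lattice is tied to a reference geometry: with
#' knot spacing `h` (mm per axis), coefficient `k` (1-based) along an axis
#' sits at world coordinate `origin + (k - 2) * h`, so the lattice extends one
#' knot beyond each face of the reference grid and every voxel centre has
#' full 4-knot support per axis. Coefficients per component:
#' `K = ceiling(extent / h) + 3` where `extent` is the voxel-centre extent.
#'
#' @param coeffs list of three identically shaped 3D arrays (mm): the x, y, z
#'   displacement coefficient grids.
#' @param knot_spacing scalar or length-3 knot spacing in mm (> 0).
#' @param ref_geom a [vol_geometry()] (or object with one): the reference
#'   grid the warp is defined over.
#' @return object of class `spline_warp`.
#' @seealso [identity_warp()], [evaluate_displacement()], [compute_jacobians()]
#' @export
spline_warp <- function(coeffs, knot_spacing, ref_geom) {
  ref_geom <- geometry_of(ref_geom)
  knot_spacing <- rep_len(as.numeric(knot_spacing), 3L)
  if (any(knot_spacing <= 0)) stop("knot_spacing must be positive (mm)")
  K <- warp_coef_dim(ref_geom, knot_spacing)
  stopifnot(is.list(coeffs), length(coeffs) == 3L)
  for (c_ in coeffs)
    if (!all(dim(c_) == K))
      stop("coefficient grids must have dim ", paste(K, collapse = "x"),
           " for this geometry/knot spacing")
  structure(list(coeffs = coeffs, knot_spacing = knot_spacing,
                 ref_geom = ref_geom, K = K),
            class = "spline_warp")
}

#' @rdname spline_warp
#' @export
identity_warp <- function(ref_geom, knot_spacing) {
  ref_geom <- geometry_of(ref_geom)
  K <- warp_coef_dim(ref_geom, rep_len(as.numeric(knot_spacing), 3L))
  z <- array(0, K)
  spline_warp(list(z, z, z), knot_spacing, ref_geom)
}

# Coefficients per axis needed to cover the voxel-centre extent with one
# extra knot beyond each face.
warp_coef_dim <- function(geom, h) {
  ext <- (geom$shape - 1) * geom$voxel_size
  as.integer(ceiling(round(ext / h, 9)) + 3L)
}

#' Number of spline coefficients of a warp
#'
#' `M` is the coefficient count per displacement component; the parameter
#' vector of the registration has length `3M` (x-block, y-block, z-block).
#' @param warp a [spline_warp()].
#' @export
n_coef <- function(warp) prod(warp$K)

#' @export
print.spline_warp <- function(x, ...) {
  cat("<spline_warp> knots ", paste(x$K, collapse = " x "),
      " per component (3M = ", 3 * n_coef(x), " parameters), spacing ",
      paste(format(x$knot_spacing), collapse = " x "), " mm\n", sep = "")
  mx <- max(abs(unlist(x$coeffs)))
  cat("  max |coefficient| ", format(mx), " mm; reference ",
      paste(x$ref_geom$shape, collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

# Flatten / unflatten the 3M parameter vector (x-block, y-block, z-block).
warp_par <- function(warp) c(warp$coeffs[[1]], warp$coeffs[[2]], warp$coeffs[[3]])

warp_set_par <- function(warp, par) {
  M <- n_coef(warp)
  for (i in 1:3)
    warp$coeffs[[i]] <- array(par[((i - 1) * M + 1):(i * M)], warp$K)
  warp
}

# --- 1D basis matrices -----------------------------------------------------

# Sparse n x K matrix of cubic B-spline basis values (deriv = 0) or first
# spatial derivatives in 1/mm (deriv = 1) at coordinates x_mm along one axis
# of the knot lattice. Errors if x falls outside the lattice support.
spline_basis_1d <- function(x_mm, origin, h, K, deriv = 0L) {
  u <- (x_mm - origin) / h + 2          # knot k sits at u = k
  if (any(u < 1 - 1e-9) || any(u > K + 1e-9))
    stop("points outside the spline support: grid not covered by this warp")
  n <- length(u)
  i0 <- floor(u)
  ks <- outer(i0, (-1):2, `+`)
  tt <- u - ks
  w <- if (deriv == 0L) bspline3(tt) else bspline3_d1(tt) / h
  keep <- ks >= 1 & ks <= K
  if (any(abs(w[!keep]) > 1e-6))
    stop("spline support does not cover the requested grid")
  Matrix::sparseMatrix(i = row(ks)[keep], j = ks[keep], x = w[keep],
                       dims = c(n, K))
}

# The three per-axis basis matrices for evaluating on a grid geometry;
# deriv_axis = 0 gives value bases, 1..3 differentiates along that axis.
warp_axis_bases <- function(warp, geom, deriv_axis = 0L) {
  lapply(1:3, function(a)
    spline_basis_1d(axis_coords(geom, a), warp$ref_geom$origin[a],
                    warp$knot_spacing[a], warp$K[a],
                    deriv = as.integer(a == deriv_axis)))
}

apply_separable <- function(coef, bases) {
  out <- coef
  for (a in 1:3) out <- apply_axis(out, bases[[a]], a)
  out
}

# --- evaluation ------------------------------------------------------------

#' Evaluate the displacement field of a warp on a grid
#'
#' Tensor-product cubic B-spline evaluation of the three displacement
#' components at the voxel centres of `geom` (default: the warp's own
#' reference grid).
#'
#' @param warp a [spline_warp()].
#' @param geom a [vol_geometry()]; must lie inside the spline support.
#' @return 4D array `c(shape, 3)` of displacements in mm.
#' @export
evaluate_displacement <- function(warp, geom = warp$ref_geom) {
  geom <- geometry_of(geom)
  bases <- warp_axis_bases(warp, geom, 0L)
  out <- array(0, c(geom$shape, 3L))
  for (i in 1:3) out[, , , i] <- apply_separable(warp$coeffs[[i]], bases)
  out
}

# Displacement at scattered world points (N x 3, mm). Used by the warp
# inverter and for dense-export checks; grid evaluation uses the separable
# path above instead.
displacement_at_points <- function(warp, pts) {
  w <- idx <- vector("list", 3L)
  for (a in 1:3) {
    h <- warp$knot_spacing[a]
    u <- (pts[, a] - warp$ref_geom$origin[a]) / h + 2
    # clamp to the fully covered domain (constant extrapolation beyond the
    # reference extent) so partition of unity holds at every query point
    u <- pmin(pmax(u, 2), warp$K[a] - 1)
    i0 <- floor(u)
    i0 <- pmin(i0, warp$K[a] - 2)      # keep the 4-stencil in range
    ks <- outer(i0, (-1):2, `+`)
    wt <- bspline3(u - ks)
    wt[ks < 1 | ks > warp$K[a]] <- 0
    ks <- pmin(pmax(ks, 1), warp$K[a])
    w[[a]] <- wt; idx[[a]] <- ks
  }
  K <- warp$K
  out <- matrix(0, nrow(pts), 3L)
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    wt <- w[[1]][, a] * w[[2]][, b] * w[[3]][, cc]
    lin <- idx[[1]][, a] + K[1] * ((idx[[2]][, b] - 1) + K[2] * (idx[[3]][, cc] - 1))
    for (i in 1:3) out[, i] <- out[, i] + wt * warp$coeffs[[i]][lin]
  }
  out
}

#' Per-voxel Jacobians of a warp
#'
#' Computes the local Jacobian `J = I + d(dx,dy,dz)/d(x,y,z)` of the
#' transformation at every voxel centre of `geom`, analytically from the
#' spline spatial derivatives and with respect to world mm coordinates (so
#' the identity warp gives `J = I` whatever the voxel anisotropy). Also
#' returns determinants and singular values (descending), the quantities the
#' regularisation penalties and warp-quality metrics are built from.
#'
#' @inheritParams evaluate_displacement
#' @param singvals compute singular values (closed-form symmetric 3x3
#'   eigensolve); disable to save time when only determinants are needed.
#' @return object of class `jacobian_field`: fields `J` (N x 9, row-major),
#'   `det` (3D array), `singvals` (N x 3 or NULL), `geom`.
#' @export
compute_jacobians <- function(warp, geom = warp$ref_geom, singvals = TRUE) {
  geom <- geometry_of(geom)
  n <- prod(geom$shape)
  J <- m3_identity(n)
  for (j in 1:3) {
    bases <- warp_axis_bases(warp, geom, j)
    for (i in 1:3)
      J[, m3col(i, j)] <- J[, m3col(i, j)] +
        as.vector(apply_separable(warp$coeffs[[i]], bases))
  }
  dt <- m3_det(J)
  structure(list(J = J, det = array(dt, geom$shape),
                 singvals = if (singvals) m3_singvals(J) else NULL,
                 geom = geom),
            class = "jacobian_field")
}

#' @export
print.jacobian_field <- function(x, ...) {
  cat("<jacobian_field> ", paste(x$geom$shape, collapse = " x "),
      " voxels; det range [", format(min(x$det)), ", ",
      format(max(x$det)), "]\n", sep = "")
  invisible(x)
}

# Build a jacobian_field directly from an N x 9 matrix (tests, dense fields).
jacobian_field_from_matrix <- function(J, geom = NULL, singvals = TRUE) {
  n <- nrow(J)
  if (is.null(geom)) geom <- vol_geometry(c(2, 2, 2))  # dummy geometry
  shape <- if (prod(geom$shape) == n) geom$shape else c(n, 1, 1)
  structure(list(J = J, det = array(m3_det(J), shape),
                 singvals = if (singvals) m3_singvals(J) else NULL,
                 geom = geom),
            class = "jacobian_field")
}

# --- resampling ------------------------------------------------------------

#' Resample an image through a warp
#'
#' The output lives on `geom` (default: the warp's reference grid); the value
#' at voxel centre `x` is the moving image sampled at `t(x) = x + d(x)`.
#' Interpolation: `"cubic"` (prefiltered interpolating cubic B-spline,
#' the similarity default), `"linear"`, or `"nearest"` (labels). Samples
#' falling outside the moving image take `fill`.
#'
#' @param moving an [image_volume()].
#' @param warp a [spline_warp()].
#' @param interpolation one of `"cubic"`, `"linear"`, `"nearest"`.
#' @param fill out-of-field value (0 = background convention).
#' @param geom output grid, a [vol_geometry()].
#' @return resampled [image_volume()] on `geom`.
#' @export
resample_image <- function(moving, warp,
                           interpolation = c("cubic", "linear", "nearest"),
                           fill = 0, geom = warp$ref_geom) {
  interpolation <- match.arg(interpolation)
  geom <- geometry_of(geom)
  vox <- warped_voxel_coords(moving, warp, geom)
  s <- switch(interpolation,
    cubic   = sample_volume_coefs(bspline_prefilter(moving$data), vox, fill),
    linear  = sample_volume_linear(moving$data, vox, fill),
    nearest = sample_volume_nearest(moving$data, vox, fill))
  # direct construction: a non-finite fill value is a legitimate choice here
  structure(list(data = array(s$value, geom$shape),
                 voxel_size = geom$voxel_size, origin = geom$origin),
            class = "image_volume")
}

# Fractional 0-based voxel coordinates into `moving` of the warped positions
# t(x) for every voxel centre x of geom.
warped_voxel_coords <- function(moving, warp, geom) {
  d <- evaluate_displacement(warp, geom)
  n <- prod(geom$shape)
  dim(d) <- c(n, 3L)
  for (a in 1:3) {
    x <- axis_coords(geom, a)
    rep_x <- switch(a,
      rep(x, times = prod(geom$shape[2:3])),
      rep(rep(x, each = geom$shape[1]), times = geom$shape[3]),
      rep(x, each = prod(geom$shape[1:2])))
    d[, a] <- (rep_x + d[, a] - moving$origin[a]) / moving$voxel_size[a]
  }
  d
}

# --- inversion -------------------------------------------------------------

#' Numerical inverse of a warp
#'
#' Fixed-point iteration `d_inv(x) <- -d(x + d_inv(x))` on the voxel grid,
#' valid for diffeomorphic warps (min Jacobian determinant > 0; refused
#' otherwise). Returns the dense inverse displacement field together with
#' composition residual statistics `||t(t^{-1}(x)) - x||`.
#'
#' @param warp a [spline_warp()] with positive Jacobian determinants.
#' @param tol convergence tolerance on the max update, mm.
#' @param max_iter iteration cap.
#' @param geom grid on which to invert (default: reference grid).
#' @return list with `displacement` (4D array, mm), `geom`, `converged`,
#'   `iterations`, and `residual` summary stats (mm).
#' @export
invert_warp <- function(warp, tol = 0.01, max_iter = 50L,
                        geom = warp$ref_geom) {
  geom <- geometry_of(geom)
  jac <- compute_jacobians(warp, geom, singvals = FALSE)
  if (min(jac$det) <= 0)
    stop("invert_warp: warp is not diffeomorphic on this grid (min |J| = ",
         format(min(jac$det)), ")")
  n <- prod(geom$shape)
  x <- matrix(0, n, 3L)
  for (a in 1:3) {
    xa <- axis_coords(geom, a)
    x[, a] <- switch(a,
      rep(xa, times = prod(geom$shape[2:3])),
      rep(rep(xa, each = geom$shape[1]), times = geom$shape[3]),
      rep(xa, each = prod(geom$shape[1:2])))
  }
  dinv <- -displacement_at_points(warp, x)   # first guess: negated forward
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    upd <- -displacement_at_points(warp, x + dinv)
    delta <- sqrt(rowSums((upd - dinv)^2))
    dinv <- upd
    if (max(delta) < tol) { converged <- TRUE; break }
  }
  res <- sqrt(rowSums((dinv + displacement_at_points(warp, x + dinv))^2))
  if (!converged)
    warning("invert_warp: not converged after ", it,
            " iterations (max residual ", format(max(res)), " mm)")
  list(displacement = array(dinv, c(geom$shape, 3L)), geom = geom,
       converged = converged, iterations = it,
       residual = c(median = stats::median(res), mean = mean(res),
                    max = max(res),
                    frac_below_tol = mean(res < tol)))
}

# --- refitting / level transfer -------------------------------------------

# Least-squares fit of spline coefficients (new lattice: geometry + spacing)
# to a dense displacement field sampled on `geom`. Used to carry the warp
# from one pyramid level to the next; cubic-spline refinement makes this
# near-exact when the spacing divides the old one.
fit_warp_to_field <- function(disp, geom, knot_spacing, ref_geom = geom,
                              lambda = 1e-8) {
  geom <- geometry_of(geom)
  new <- identity_warp(ref_geom, knot_spacing)
  bases <- warp_axis_bases(new, geom, 0L)
  Kp <- Matrix::kronecker(bases[[3]], Matrix::kronecker(bases[[2]], bases[[1]]))
  A <- Matrix::crossprod(Kp)
  dg <- Matrix::diag(A)
  A <- A + lambda * mean(dg) * Matrix::Diagonal(ncol(Kp))
  n <- prod(geom$shape)
  dim(disp) <- c(n, 3L)
  for (i in 1:3) {
    rhs <- Matrix::crossprod(Kp, disp[, i])
    ci <- Matrix::solve(A, rhs)
    new$coeffs[[i]] <- array(as.numeric(ci), new$K)
  }
  dim(disp) <- c(geom$shape, 3L)
  new
}

# Re-express a warp on a finer knot lattice (optionally a new reference).
refine_warp <- function(warp, knot_spacing, geom = warp$ref_geom) {
  geom <- geometry_of(geom)
  disp <- evaluate_displacement(warp, geom)
  fit_warp_to_field(disp, geom, knot_spacing, ref_geom = warp$ref_geom)
}
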
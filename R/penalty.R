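#' Quadratic-log approximation
#'
#' `log2_approx(x) = x + 1/x - 2`, the SVD-free surrogate for `log(x)^2`
#' used throughout the penalty machinery. Exact to second order at `x = 1`
#' (`x + 1/x - 2 = (x-1)^2/x`) and symmetric under `x <-> 1/x`, so
#' expansions and contractions are treated identically.
#'
#' @param x positive numeric.
#' @return numeric of the same length.
#' @examples
#' log2_approx(2)        # 0.5, vs log(2)^2 = 0.4805
#' log2_approx(c(3, 1/3))  # identical values
#' @export
log2_approx <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("log2_approx: x must be positive")
  x + 1 / x - 2
}

# --- per-voxel densities and derivative rows -------------------------------

# Density of the SPRED penalty (SVD-free form):
#   c_n = v (1 + |J|) (tr(J'J) + tr(J^-T J^-1) - 6) / 4
# computed from the elements of J only, via tr(J^-T J^-1) = |adj J|_F^2/|J|^2.
spred_density <- function(J, det, v) {
  P <- m3_frob2(J)
  Q <- m3_frob2(m3_adjugate(J))
  v * (1 + det) * (P + Q / det^2 - 6) / 4
}

# 1 x 9 derivative rows d c_n / d J (row-major layout), closed form by the
# product rule: d|J|/dJ is the cofactor matrix, d tr(J'J)/dJ = 2J and
# d tr(J^-T J^-1)/dJ = -2 J^-T J^-1 J^-T. No SVD anywhere.
spred_density_rows <- function(J, det, v) {
  adj <- m3_adjugate(J)
  cof <- m3_transpose(adj)           # d det / dJ
  P <- m3_frob2(J)
  Q <- m3_frob2(adj)
  Jinv <- adj / det
  JitJiJit <- m3_mult(m3_transpose(Jinv), m3_mult(Jinv, m3_transpose(Jinv)))
  v * (cof * ((P + Q / det^2 - 6) / 4) + (1 + det) * (2 * J - 2 * JitJiJit) / 4)
}

# Jacobian-determinant comparison penalty: c_n = v (1 + |J|) log^2|J| with
# log^2 realised through the same x + 1/x - 2 surrogate applied to |J|^2
# (log^2 y = log^2(y^2)/4), keeping the two penalty paths consistent.
jacdet_density <- function(J, det, v) {
  v * (1 + det) * (det^2 + 1 / det^2 - 2) / 4
}

jacdet_density_rows <- function(J, det, v) {
  cof <- m3_transpose(m3_adjugate(J))
  scal <- v * ((det^2 + 1 / det^2 - 2) / 4 +
               (1 + det) * (2 * det - 2 / det^3) / 4)
  cof * scal
}

# Local rigidity comparison penalty: c_n = v ||J'J - I||_F (defined for any
# J, including folded voxels; it does not diverge at |J| -> 0).
rigidity_density <- function(J, det, v) {
  A <- m3_mult(m3_transpose(J), J)
  A[, c(1L, 5L, 9L)] <- A[, c(1L, 5L, 9L)] - 1
  v * sqrt(m3_frob2(A))
}

rigidity_density_rows <- function(J, det, v) {
  A <- m3_mult(m3_transpose(J), J)
  A[, c(1L, 5L, 9L)] <- A[, c(1L, 5L, 9L)] - 1
  phi <- sqrt(m3_frob2(A))
  # d||A||_F/dJ = 2 J A / ||A||_F ; the norm is non-smooth at A = 0, where
  # the subgradient 0 is used (rows of exactly-rigid voxels vanish).
  sel <- phi > 1e-300
  out <- 2 * m3_mult(J, A)
  out[sel, ] <- out[sel, ] / phi[sel]
  out[!sel, ] <- 0
  v * out
}

penalty_density_fun <- function(type) {
  switch(type,
    spred = spred_density, jacdet = jacdet_density,
    rigidity = rigidity_density,
    stop("unknown penalty type: ", type))
}

penalty_rows_fun <- function(type) {
  switch(type,
    spred = spred_density_rows, jacdet = jacdet_density_rows,
    rigidity = rigidity_density_rows)
}

# Does the penalty diverge for non-positive determinants?
penalty_needs_posdet <- function(type) type %in% c("spred", "jacdet")

# --- value-only interfaces on Jacobian fields ------------------------------

#' Exact SPRED penalty via singular value decomposition
#'
#' The reference form of the penalty, `sum_n v (1+|J_n|) sum_i log^2 s_i`,
#' evaluated through an explicit SVD of every Jacobian. It is the oracle the
#' SVD-free approximate path is validated against; the registration itself
#' never calls it.
#'
#' @param jac a `jacobian_field` (see [compute_jacobians()]).
#' @param v voxel volume in mm^3.
#' @return scalar penalty; `Inf` if any determinant is non-positive.
#' @export
spred_value_exact <- function(jac, v = voxel_volume(jac$geom)) {
  det <- as.vector(jac$det)
  if (any(det <= 0)) return(Inf)
  n <- nrow(jac$J)
  tot <- 0
  for (k in seq_len(n)) {
    s <- svd(matrix(jac$J[k, ], 3, 3, byrow = TRUE), nu = 0, nv = 0)$d
    tot <- tot + v * (1 + det[k]) * sum(log(s)^2)
  }
  tot
}

#' SVD-free SPRED penalty value and densities
#'
#' `sum_n v (1+|J_n|) tr(J_n' J_n + J_n^-T J_n^-1 - 2 I)/4`, an explicit
#' function of the Jacobian elements (no SVD). Equals the exact penalty to
#' second order around the identity.
#'
#' @inheritParams spred_value_exact
#' @return list with `value` (scalar, `Inf` on non-positive determinants)
#'   and `densities` (per-voxel contributions, same shape as `jac$det`).
#' @export
spred_value_approx <- function(jac, v = voxel_volume(jac$geom)) {
  det <- as.vector(jac$det)
  if (any(det <= 0)) {
    dens <- rep(Inf, length(det))
    dens[det > 0] <- spred_density(jac$J[det > 0, , drop = FALSE],
                                   det[det > 0], v)
    return(list(value = Inf, densities = array(dens, dim(jac$det))))
  }
  dens <- spred_density(jac$J, det, v)
  list(value = sum(dens), densities = array(dens, dim(jac$det)))
}

# --- full penalty engine ---------------------------------------------------

# Kronecker-expanded basis matrices: K0 (values) and K1..K3 (spatial
# derivative along that axis), each n_voxels x M sparse. The columns are in
# coefficient-array (column-major) order, matching warp_par().
warp_kron_bases <- function(warp, geom, derivs = TRUE) {
  kb <- list()
  b0 <- warp_axis_bases(warp, geom, 0L)
  kron3 <- function(b) Matrix::kronecker(b[[3]], Matrix::kronecker(b[[2]], b[[1]]))
  kb$K0 <- kron3(b0)
  if (derivs)
    for (j in 1:3) kb[[paste0("K", j)]] <- kron3(warp_axis_bases(warp, geom, j))
  kb
}

#' Regularisation penalty of a warp with derivatives
#'
#' Evaluates one of the three regularisers at the voxel centres of `geom`
#' and, on request, its analytic gradient (length `3M`) and sparse
#' Gauss-Newton Hessian (`3M x 3M`) with respect to the spline coefficients.
#' The Hessian is `H = sum_n 1/(2 c_n) g_n g_n'` with `g_n = d c_n / dw`,
#' assembled from per-voxel 1x9 derivative rows contracted against the
#' spline spatial-derivative stencils; only coefficient pairs with
#' overlapping support produce non-zeros. Voxels with `c_n` below
#' `floor_rel * v` are skipped in the Hessian (the `1/(2 c_n)` factor is
#' singular at the penalty's minimum).
#'
#' For `"spred"` and `"jacdet"` a non-positive determinant anywhere makes
#' the penalty infinite: the result carries `value = Inf` and no
#' derivatives, which the optimiser treats as an automatic step rejection.
#'
#' @param warp a [spline_warp()].
#' @param type `"spred"`, `"jacdet"` or `"rigidity"`.
#' @param geom evaluation grid (default: the warp's reference grid).
#' @param derivatives `"none"`, `"gradient"` or `"hessian"` (implies
#'   gradient).
#' @param v per-sample volume weight, mm^3 (default: voxel volume of `geom`).
#' @param floor_rel relative density floor for the Hessian weight.
#' @param kb precomputed [Kronecker basis matrices][warp_penalty] (internal
#'   reuse across optimiser iterations); leave `NULL` normally.
#' @return object of class `penalty_result`: `value`, `densities` (array),
#'   `gradient`, `hessian`, plus bookkeeping fields.
#' @export
warp_penalty <- function(warp, type = c("spred", "jacdet", "rigidity"),
                         geom = warp$ref_geom,
                         derivatives = c("hessian", "gradient", "none"),
                         v = NULL, floor_rel = 1e-12, kb = NULL) {
  type <- match.arg(type)
  derivatives <- match.arg(derivatives)
  geom <- geometry_of(geom)
  if (is.null(v)) v <- voxel_volume(geom)
  jac <- compute_jacobians(warp, geom, singvals = FALSE)
  det <- as.vector(jac$det)
  M <- n_coef(warp)
  if (penalty_needs_posdet(type) && any(det <= 0)) {
    dens <- rep(Inf, length(det))
    ok <- det > 0
    dens[ok] <- penalty_density_fun(type)(jac$J[ok, , drop = FALSE], det[ok], v)
    return(structure(list(value = Inf, densities = array(dens, geom$shape),
                          gradient = NULL, hessian = NULL, type = type,
                          geom = geom, v = v, min_det = min(det),
                          finite = FALSE),
                     class = "penalty_result"))
  }
  dens <- penalty_density_fun(type)(jac$J, det, v)
  grad <- NULL; H <- NULL
  if (derivatives != "none") {
    rows <- penalty_rows_fun(type)(jac$J, det, v)
    if (is.null(kb)) kb <- warp_kron_bases(warp, geom)
    grad <- numeric(3L * M)
    for (i in 1:3) {
      acc <- numeric(M)
      for (j in 1:3)
        acc <- acc + as.numeric(
          Matrix::crossprod(kb[[paste0("K", j)]], rows[, m3col(i, j)]))
      grad[((i - 1) * M + 1):(i * M)] <- acc
    }
    if (derivatives == "hessian") {
      w <- 1 / (2 * dens)
      sel <- dens >= floor_rel * v
      if (any(sel)) {
        G <- penalty_coef_jacobian(rows, kb, sel)
        H <- Matrix::crossprod(sqrt(w[sel]) * G)
        H <- methods::as(Matrix::forceSymmetric(H), "CsparseMatrix")
      } else {
        H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(3L * M, 3L * M), symmetric = TRUE)
        H <- methods::as(H, "CsparseMatrix")
      }
    }
  }
  structure(list(value = sum(dens), densities = array(dens, geom$shape),
                 gradient = grad, hessian = H, type = type, geom = geom,
                 v = v, min_det = min(det), finite = TRUE),
            class = "penalty_result")
}

# Sparse n_sel x 3M matrix G with G[n, m] = d c_n / d w_m, from per-voxel
# rows and the Kronecker stencils; sel restricts to the voxels kept.
penalty_coef_jacobian <- function(rows, kb, sel = NULL) {
  blocks <- vector("list", 3L)
  for (i in 1:3) {
    Gi <- NULL
    for (j in 1:3) {
      term <- rows[, m3col(i, j)] * kb[[paste0("K", j)]]
      Gi <- if (is.null(Gi)) term else Gi + term
    }
    blocks[[i]] <- if (is.null(sel)) Gi else Gi[sel, , drop = FALSE]
  }
  do.call(cbind, blocks)
}

#' @export
print.penalty_result <- function(x, ...) {
  cat("<penalty_result> ", x$type, ": value ", format(x$value),
      ", min |J| ", format(x$min_det), "\n", sep = "")
  if (!is.null(x$gradient))
    cat("  |gradient| ", format(sqrt(sum(x$gradient^2))),
        if (!is.null(x$hessian)) paste0(", Hessian ", nrow(x$hessian), "^2 sparse"),
        "\n", sep = "")
  invisible(x)
}

#' @rdname warp_penalty
#' @param ... passed on to [warp_penalty()].
#' @export
spred_penalty <- function(warp, ...) warp_penalty(warp, type = "spred", ...)

#' @rdname warp_penalty
#' @export
jacdet_penalty <- function(warp, ...) warp_penalty(warp, type = "jacdet", ...)

#' @rdname warp_penalty
#' @export
rigidity_penalty <- function(warp, ...) warp_penalty(warp, type = "rigidity", ...)

#' @rdname warp_penalty
#' @export
spred_grad <- function(warp, geom = warp$ref_geom, v = NULL) {
  warp_penalty(warp, "spred", geom, "gradient", v = v)$gradient
}

#' @rdname warp_penalty
#' @export
spred_hessian <- function(warp, geom = warp$ref_geom, v = NULL, ...) {
  warp_penalty(warp, "spred", geom, "hessian", v = v, ...)$hessian
}
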
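# Shared fixture builders. Everything is generated in code from fixed
# seeds; nothing is read from disk.

# A small reference geometry with anisotropy to catch mm/voxel mix-ups.
small_geom <- function(shape = c(12, 10, 11), voxel = c(2, 2, 2)) {
  vol_geometry(shape, voxel)
}

# Random smooth spline warp with controllable coefficient scale (mm).
random_warp <- function(geom, knot = c(8, 8, 8), sd = 0.5, seed = 1) {
  w <- identity_warp(geom, knot)
  set.seed(seed)
  w$coeffs <- lapply(1:3, function(i) array(rnorm(prod(w$K), sd = sd), w$K))
  w
}

# Random rotation matrix (Haar-ish via QR, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# N x 9 field of Jacobians J = U diag(s) V' with log-singular values drawn
# from the lognormal prior the penalty encodes, truncated to [1/3, 3].
random_jacobian_field <- function(n, sd_log = log(3) / 3, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(k) {
    s <- exp(pmin(pmax(rnorm(3, 0, sd_log), -log(3)), log(3)))
    as.vector(t(random_rotation() %*% diag(s) %*% t(random_rotation())))
  }, numeric(9)))
}

# Wrap an N x 9 matrix as a jacobian_field (dummy geometry, v = 1).
as_jac_field <- function(J) {
  jacobian_field_from_matrix <- getFromNamespace("jacobian_field_from_matrix",
                                                 "warpreg")
  jacobian_field_from_matrix(J, vol_geometry(c(2, 2, 2)))
}

# Single-matrix jacobian field from a 3x3 matrix.
jac1 <- function(M) as_jac_field(matrix(as.vector(t(M)), 1, 9))

# Random test image on a geometry.
random_image <- function(geom, seed = 1) {
  set.seed(seed)
  image_volume(array(rnorm(prod(geom$shape)), geom$shape),
               geom$voxel_size, geom$origin)
}

# World-mm coordinates of all voxel centres of a geometry, N x 3.
grid_points <- function(g) {
  xs <- lapply(1:3, function(a)
    g$origin[a] + (seq_len(g$shape[a]) - 1) * g$voxel_size[a])
  cbind(rep(xs[[1]], times = prod(g$shape[2:3])),
        rep(rep(xs[[2]], each = g$shape[1]), times = g$shape[3]),
        rep(xs[[3]], each = prod(g$shape[1:2])))
}

# Central finite difference of a scalar function of the warp parameters.
fd_gradient <- function(fun, warp, idx, eps = 1e-4) {
  par <- getFromNamespace("warp_par", "warpreg")(warp)
  setp <- getFromNamespace("warp_set_par", "warpreg")
  vapply(idx, function(m) {
    p1 <- par; p1[m] <- p1[m] + eps
    p2 <- par; p2[m] <- p2[m] - eps
    (fun(setp(warp, p1)) - fun(setp(warp, p2))) / (2 * eps)
  }, numeric(1))
}
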
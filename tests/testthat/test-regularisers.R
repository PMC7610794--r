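# The SPRED penalty (exact and SVD-free forms), the two comparison
# penalties, and their analytic derivatives.

test_that("log2_approx has the stated values and symmetry", {
  expect_equal(log2_approx(1), 0)
  expect_equal(log2_approx(2), 0.5)
  # ~4% relative error at a twofold scaling
  expect_lt(abs(log2_approx(2) - log(2)^2) / log(2)^2, 0.05)
  x <- exp(runif(50, -2, 2))
  expect_equal(log2_approx(x), log2_approx(1 / x), tolerance = 1e-12)
  expect_error(log2_approx(0))
  expect_error(log2_approx(-1))
})

test_that("penalty hand values on axis-aligned Jacobians", {
  jd2 <- jac1(diag(c(2, 1, 1)))
  jdh <- jac1(diag(c(0.5, 1, 1)))
  # SVD-free SPRED: (1+2)(4 + 1/4 + 2 - 6)/4 = 1.6875
  expect_equal(spred_value_approx(jd2, v = 1)$value, 1.6875)
  # contraction: 1.5 * 2.25 / 4 = 0.84375; two contractions = one expansion
  expect_equal(spred_value_approx(jdh, v = 1)$value, 0.84375)
  expect_equal(2 * spred_value_approx(jdh, v = 1)$value,
               spred_value_approx(jd2, v = 1)$value)
  # exact (SVD) form: 3 log^2 2
  expect_equal(spred_value_exact(jd2, v = 1), 3 * log(2)^2, tolerance = 1e-12)
  # identity and pure rotations carry no penalty
  expect_equal(spred_value_exact(jac1(diag(3)), v = 1), 0)
  expect_equal(spred_value_approx(jac1(diag(3)), v = 1)$value, 0)
  set.seed(1)
  R <- random_rotation()
  expect_equal(spred_value_exact(jac1(R), v = 1), 0, tolerance = 1e-12)
  expect_equal(spred_value_approx(jac1(R), v = 1)$value, 0, tolerance = 1e-12)
})

test_that("non-positive determinants give an infinite penalty sentinel", {
  jneg <- jac1(diag(c(-1, 1, 1)))
  expect_equal(spred_value_exact(jneg, v = 1), Inf)
  expect_equal(spred_value_approx(jneg, v = 1)$value, Inf)
  g <- small_geom(shape = c(8, 8, 8))
  w <- identity_warp(g, c(8, 8, 8))
  w$coeffs[[1]] <- array(rnorm(prod(w$K), sd = 15), w$K)
  if (min(compute_jacobians(w, singvals = FALSE)$det) <= 0) {
    pr <- warp_penalty(w, "spred", derivatives = "none")
    expect_false(pr$finite)
    expect_equal(pr$value, Inf)
    expect_null(pr$gradient)
  }
})

test_that("exact and approximate SPRED agree under the lognormal prior", {
  J <- random_jacobian_field(1500, seed = 2)
  jac <- as_jac_field(J)
  ex <- spred_value_exact(jac, v = 1)
  ap <- spred_value_approx(jac, v = 1)$value
  expect_lt(abs(ap - ex) / ex, 0.15)
  expect_gt(ap, ex)   # the surrogate over-estimates log^2
})

test_that("SPRED symmetries: inversion of the density and global rotations", {
  J <- random_jacobian_field(400, seed = 3)
  jac <- as_jac_field(J)
  det <- as.vector(jac$det)
  dens <- spred_value_approx(jac, v = 1)$densities
  m3 <- list(inv = getFromNamespace("m3_inverse", "warpreg"),
             mult = getFromNamespace("m3_mult", "warpreg"))
  Jinv <- m3$inv(J)
  jinv <- as_jac_field(Jinv)
  dens_inv <- spred_value_approx(jinv, v = 1)$densities
  # per-voxel density / (1 + |J|) is invariant under J -> J^-1
  expect_equal(as.vector(dens) / (1 + det),
               as.vector(dens_inv) / (1 + as.vector(jinv$det)),
               tolerance = 1e-9)
  # pre/post rotation leaves the penalty unchanged
  set.seed(4)
  R1 <- random_rotation(); R2 <- random_rotation()
  n <- nrow(J)
  R1f <- matrix(rep(as.vector(t(R1)), each = n), n, 9)
  R2f <- matrix(rep(as.vector(t(R2)), each = n), n, 9)
  Jrot <- m3$mult(R1f, m3$mult(J, R2f))
  expect_equal(spred_value_approx(as_jac_field(Jrot), v = 1)$value,
               spred_value_approx(jac, v = 1)$value, tolerance = 1e-9)
  expect_equal(spred_value_exact(as_jac_field(Jrot), v = 1),
               spred_value_exact(jac, v = 1), tolerance = 1e-8)
})

test_that("comparison penalties match their hand values", {
  # volume-only: |J| = 1 escapes the jacdet penalty despite shape change
  pr <- warp_penalty
  jd <- function(M) {
    f <- getFromNamespace("jacdet_density", "warpreg")
    J <- matrix(as.vector(t(M)), 1, 9)
    f(J, det(M), 1)
  }
  rg <- function(M) {
    f <- getFromNamespace("rigidity_density", "warpreg")
    J <- matrix(as.vector(t(M)), 1, 9)
    f(J, det(M), 1)
  }
  expect_equal(jd(diag(3)), 0)
  expect_equal(jd(diag(c(2, 0.5, 1))), 0)            # det = 1
  expect_equal(jd(diag(c(2, 1, 1))), 1.6875)         # (1+2)(4+1/4-2)/4
  expect_equal(rg(diag(3)), 0)
  set.seed(5)
  expect_equal(rg(random_rotation()), 0, tolerance = 1e-12)
  expect_equal(rg(diag(c(2, 1, 1))), 3)              # ||diag(3,0,0)||_F
})

test_that("SPRED and jacdet penalties diverge monotonically towards folding", {
  # family J(t) = diag(1 - t, 1, 1): min det -> 0+ as t -> 1-
  ts <- seq(0.1, 0.95, by = 0.05)
  sp <- vapply(ts, function(t)
    spred_value_approx(jac1(diag(c(1 - t, 1, 1))), v = 1)$value, numeric(1))
  jdf <- getFromNamespace("jacdet_density", "warpreg")
  jd <- vapply(ts, function(t) {
    J <- matrix(as.vector(t(diag(c(1 - t, 1, 1)))), 1, 9)
    jdf(J, 1 - t, 1)
  }, numeric(1))
  expect_true(all(diff(sp) > 0))
  expect_true(all(diff(jd) > 0))
  expect_gt(sp[length(sp)], 50)   # large already at det 0.05
})

test_that("analytic penalty gradients match finite differences", {
  g <- small_geom(shape = c(10, 9, 8))
  w <- random_warp(g, knot = c(6, 6, 6), sd = 0.6, seed = 6)
  expect_gt(min(compute_jacobians(w, singvals = FALSE)$det), 0)
  set.seed(7)
  for (ty in c("spred", "jacdet", "rigidity")) {
    pr <- warp_penalty(w, ty, derivatives = "gradient")
    idx <- sample(3 * n_coef(w), 20)
    fd <- fd_gradient(function(wp)
      warp_penalty(wp, ty, derivatives = "none")$value, w, idx)
    expect_lt(max(abs(fd - pr$gradient[idx])) / max(abs(fd)), 1e-4)
  }
  # the identity warp sits at the global minimum: zero gradient
  w0 <- identity_warp(g, c(6, 6, 6))
  expect_equal(max(abs(warp_penalty(w0, "spred",
                                    derivatives = "gradient")$gradient)), 0)
})

test_that("sparse GN Hessian equals the dense outer-product oracle and is PSD", {
  g <- small_geom(shape = c(8, 8, 8))
  w <- random_warp(g, knot = c(8, 8, 8), sd = 0.5, seed = 8)
  v <- voxel_volume(g)
  pr <- warp_penalty(w, "spred", derivatives = "hessian")
  ns <- getFromNamespace
  jac <- compute_jacobians(w, singvals = FALSE)
  rows <- ns("spred_density_rows", "warpreg")(jac$J, as.vector(jac$det), v)
  kb <- ns("warp_kron_bases", "warpreg")(w, g)
  G <- as.matrix(ns("penalty_coef_jacobian", "warpreg")(rows, kb))
  dens <- as.vector(pr$densities)
  Hd <- matrix(0, ncol(G), ncol(G))
  for (n in which(dens >= 1e-12 * v))
    Hd <- Hd + (1 / (2 * dens[n])) * tcrossprod(G[n, ])
  expect_equal(as.matrix(pr$hessian), Hd, tolerance = 1e-10,
               ignore_attr = TRUE)
  ev <- eigen(Hd, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(abs(ev)))
  # identity warp: all densities floored away, H = 0
  H0 <- warp_penalty(identity_warp(g, c(8, 8, 8)), "spred",
                     derivatives = "hessian")$hessian
  expect_equal(length(H0@x), 0)
})
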
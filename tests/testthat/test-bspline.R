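# The free-form deformation: evaluation, Jacobians, resampling, inversion.

test_that("zero coefficients give the identity transform everywhere", {
  g <- small_geom()
  w <- identity_warp(g, c(8, 8, 8))
  d <- evaluate_displacement(w)
  expect_equal(max(abs(d)), 0)
  jac <- compute_jacobians(w)
  expect_equal(as.vector(jac$det), rep(1, prod(g$shape)))
  expect_equal(max(abs(jac$singvals - 1)), 0, tolerance = 1e-12)
})

test_that("cubic B-splines reproduce linear coefficient ramps exactly", {
  g <- small_geom(voxel = c(2, 1.5, 2.5))   # anisotropic on purpose
  h <- c(8, 6, 10)
  w <- identity_warp(g, h)
  a <- 0.05
  centres <- g$origin[1] + ((1:w$K[1]) - 2) * h[1]
  w$coeffs[[1]] <- array(rep(a * centres, times = prod(w$K[2:3])), w$K)
  d <- evaluate_displacement(w)
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$voxel_size[1]
  expected <- array(rep(a * xs, times = prod(g$shape[2:3])), g$shape)
  expect_equal(d[, , , 1], expected, tolerance = 1e-12)
  # constant Jacobian diag(1 + a, 1, 1)
  jac <- compute_jacobians(w)
  expect_equal(range(jac$J[, 1]), c(1 + a, 1 + a), tolerance = 1e-12)
  expect_equal(range(jac$det), c(1 + a, 1 + a), tolerance = 1e-12)
})

test_that("a single unit coefficient reproduces the tensor-product kernel", {
  g <- small_geom(shape = c(17, 17, 17), voxel = c(1, 1, 1))
  h <- c(4, 4, 4)
  w <- identity_warp(g, h)
  k0 <- c(4, 4, 4)   # interior knot; world position (k0 - 2) * h
  w$coeffs[[2]][k0[1], k0[2], k0[3]] <- 1
  d <- evaluate_displacement(w)
  knot_mm <- (k0 - 2) * h
  bspline3 <- getFromNamespace("bspline3", "warpreg")
  for (a in 1:3) stopifnot(g$origin[a] == 0)
  xs <- lapply(1:3, function(a) (seq_len(g$shape[a]) - 1) * g$voxel_size[a])
  expected <- outer(outer(bspline3((xs[[1]] - knot_mm[1]) / h[1]),
                          bspline3((xs[[2]] - knot_mm[2]) / h[2])),
                    bspline3((xs[[3]] - knot_mm[3]) / h[3]))
  expect_equal(d[, , , 2], expected, tolerance = 1e-12)
  # maximum at the knot, support 4 knot spacings per axis
  expect_equal(which.max(d[, , , 2]),
               which(expected == max(expected)))
  expect_equal(max(abs(d[abs(xs[[1]] - knot_mm[1]) >= 2 * h[1], , , 2])), 0)
})

test_that("analytic Jacobians match finite differences of the displacement", {
  g <- small_geom()
  w <- random_warp(g, sd = 0.5, seed = 2)
  jac <- compute_jacobians(w)
  eps <- g$voxel_size[1] / 100
  for (ax in 1:3) {
    sh <- numeric(3); sh[ax] <- eps
    gp <- vol_geometry(g$shape, g$voxel_size, g$origin + sh)
    gm <- vol_geometry(g$shape, g$voxel_size, g$origin - sh)
    fd <- (evaluate_displacement(w, gp) - evaluate_displacement(w, gm)) / (2 * eps)
    for (i in 1:3) {
      analytic <- jac$J[, 3 * (i - 1) + ax] - (i == ax)
      expect_lt(max(abs(analytic - as.vector(fd[, , , i]))) /
                  max(abs(fd)), 1e-4)
    }
  }
})

test_that("determinants and singular values are mutually consistent", {
  g <- small_geom()
  jac <- compute_jacobians(random_warp(g, sd = 0.6, seed = 3))
  # det equals the numerical determinant at sampled voxels
  set.seed(4)
  for (k in sample(prod(g$shape), 25)) {
    expect_equal(as.vector(jac$det)[k],
                 det(matrix(jac$J[k, ], 3, 3, byrow = TRUE)),
                 tolerance = 1e-10)
  }
  # singular values descending, non-negative, product = |det|
  expect_true(all(jac$singvals >= 0))
  expect_true(all(jac$singvals[, 1] >= jac$singvals[, 2]))
  expect_true(all(jac$singvals[, 2] >= jac$singvals[, 3]))
  expect_equal(apply(jac$singvals, 1, prod), abs(as.vector(jac$det)),
               tolerance = 1e-8)
})

test_that("resampling: identity, integer translation, constants", {
  g <- small_geom()
  img <- random_image(g, seed = 5)
  w0 <- identity_warp(g, c(8, 8, 8))
  for (interp in c("cubic", "linear", "nearest"))
    expect_equal(resample_image(img, w0, interp)$data, img$data,
                 tolerance = 1e-12)
  # +1 voxel translation along x, nearest: exact shift with fill at the face
  wt <- identity_warp(g, c(8, 8, 8))
  wt$coeffs[[1]][] <- g$voxel_size[1]
  rt <- resample_image(img, wt, "nearest", fill = -7)
  n1 <- g$shape[1]
  expect_equal(rt$data[1:(n1 - 1), , ], img$data[2:n1, , ])
  expect_true(all(rt$data[n1, , ] == -7))
  # constant moving image stays constant inside the field of view
  cimg <- image_volume(array(3.5, g$shape), g$voxel_size, g$origin)
  wr <- random_warp(g, sd = 0.8, seed = 6)
  rc <- resample_image(cimg, wr, "cubic", fill = NA)
  expect_equal(range(rc$data[!is.na(rc$data)]), c(3.5, 3.5), tolerance = 1e-5)
  expect_error(resample_image(img, w0, "sinc"))
})

test_that("invert_warp: identity, translation, and fixture self-consistency", {
  g <- small_geom(shape = c(16, 16, 16))
  w0 <- identity_warp(g, c(8, 8, 8))
  inv0 <- invert_warp(w0)
  expect_equal(max(abs(inv0$displacement)), 0)
  expect_equal(inv0$residual[["max"]], 0)
  # pure translation u inverts to -u (exact after one iteration)
  wt <- identity_warp(g, c(8, 8, 8))
  u <- c(3, -2, 1.5)
  for (i in 1:3) wt$coeffs[[i]][] <- u[i]
  invt <- invert_warp(wt)
  for (i in 1:3)
    expect_equal(range(invt$displacement[, , , i]), rep(-u[i], 2),
                 tolerance = 1e-9)
  # random diffeomorphic warp: composition residual below tol on >= 99%
  # of interior voxels
  wd <- make_diffeo_warp(g, c(12, 12, 12), amplitude = 4, seed = 7)
  inv <- invert_warp(wd, tol = 0.01)
  interior <- array(FALSE, g$shape)
  interior[4:13, 4:13, 4:13] <- TRUE
  n <- prod(g$shape)
  res <- sqrt(rowSums((matrix(inv$displacement, n, 3) +
    getFromNamespace("displacement_at_points", "warpreg")(
      wd, grid_points(g) + matrix(inv$displacement, n, 3)))^2))
  expect_gt(mean(res[as.vector(interior)] < 0.01), 0.99)
  expect_lt(median(res[as.vector(interior)]), 0.01)
  # non-diffeomorphic warps are refused
  wbad <- identity_warp(g, c(8, 8, 8))
  wbad$coeffs[[1]] <- array(rnorm(prod(wbad$K), sd = 12), wbad$K)
  if (min(compute_jacobians(wbad, singvals = FALSE)$det) <= 0)
    expect_error(invert_warp(wbad), "diffeomorphic")
})

test_that("warp refinement preserves the displacement field", {
  g <- small_geom(shape = c(16, 14, 15))
  w <- make_diffeo_warp(g, c(12, 12, 12), amplitude = 3, seed = 8)
  refine_warp <- getFromNamespace("refine_warp", "warpreg")
  wf <- refine_warp(w, c(6, 6, 6))
  expect_lt(max(abs(evaluate_displacement(wf) - evaluate_displacement(w))),
            1e-4)
})
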
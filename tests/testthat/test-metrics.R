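# Warp-quality metrics: Jacobian-determinant statistics, CVAR, overlap.

test_that("jacdet_stats: identity, two-point distribution, sort oracle", {
  g <- small_geom(shape = c(8, 8, 8))
  st0 <- jacdet_stats(compute_jacobians(identity_warp(g, c(8, 8, 8))))
  expect_equal(unname(st0$summary[c("min", "max", "mean")]), c(1, 1, 1))
  expect_equal(st0$log_summary[["range_5_95"]], 0)
  expect_equal(sum(st0$hist$counts), prod(g$shape))

  # half the voxels diag(2,1,1), half diag(0.5,1,1): log dets +-log 2 and
  # the 5th-95th log range is exactly 2 log 2
  n <- 512
  J <- getFromNamespace("m3_identity", "warpreg")(n)
  J[1:(n / 2), 1] <- 2
  J[(n / 2 + 1):n, 1] <- 0.5
  st <- jacdet_stats(as_jac_field(J))
  expect_equal(st$log_summary[["range_5_95"]], 2 * log(2), tolerance = 1e-12)

  # percentiles agree with an independent interpolation of order statistics
  set.seed(1)
  jac <- compute_jacobians(random_warp(g, sd = 0.5, seed = 1))
  mask <- array(runif(prod(g$shape)) < 0.7, g$shape)
  st <- jacdet_stats(jac, mask)
  dets <- sort(as.vector(jac$det)[as.vector(mask)])
  manual_q <- function(x, p) {       # linear interpolation between order stats
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(st$summary[["p5"]], manual_q(dets, 0.05))
  expect_equal(st$summary[["p95"]], manual_q(dets, 0.95))
  expect_equal(st$n, sum(mask))
  expect_equal(sum(st$hist$counts), sum(mask))
})

test_that("jacdet_stats flags log stats when determinants are non-positive", {
  n <- 8
  J <- getFromNamespace("m3_identity", "warpreg")(n)
  J[1, 1] <- -0.5
  st <- jacdet_stats(as_jac_field(J))
  expect_false(st$all_positive)
  expect_null(st$log_summary)
  expect_equal(st$summary[["min"]], -0.5)
})

test_that("CVAR: hand values and invariances", {
  # isotropic maps have CVAR exactly 1
  expect_equal(cvar_map(jac1(diag(3)))$mean, 1, tolerance = 1e-12)
  expect_equal(cvar_map(jac1(diag(c(2.5, 2.5, 2.5))))$mean, 1,
               tolerance = 1e-12)
  # diag(2,1,1): (8/2)^(1/3)
  expect_equal(cvar_map(jac1(diag(c(2, 1, 1))))$mean, 4^(1 / 3),
               tolerance = 1e-12)
  # its inverse diag(.5,1,1): (1/0.5)^(1/3) = 2^(1/3)
  expect_equal(cvar_map(jac1(diag(c(0.5, 1, 1))))$mean, 2^(1 / 3),
               tolerance = 1e-12)
  # permutation of the axes (singular values) does not matter
  expect_equal(cvar_map(jac1(diag(c(1, 1, 2))))$mean, 4^(1 / 3),
               tolerance = 1e-12)
  # global rotations do not matter
  set.seed(2)
  R1 <- random_rotation(); R2 <- random_rotation()
  M <- R1 %*% diag(c(1.7, 0.9, 0.6)) %*% R2
  expect_equal(cvar_map(jac1(M))$mean,
               cvar_map(jac1(diag(c(1.7, 0.9, 0.6))))$mean,
               tolerance = 1e-9)
  # folded voxels are flagged, not silently averaged
  cv <- cvar_map(jac1(diag(c(-1, 1, 1))))
  expect_equal(cv$n_invalid, 1)
  expect_true(is.na(cv$map[1]))
})

test_that("overlap scores: identities, disjoint and half-overlapping regions", {
  a <- array(0L, c(12, 12, 6))
  a[2:5, 2:5, 2:5] <- 1L
  a[7:10, 7:10, 2:5] <- 2L
  s <- overlap_scores(a, a)
  expect_equal(s$jaccard, c(1, 1))
  expect_equal(s$dice, c(1, 1))
  expect_equal(s$sensitivity, c(1, 1))
  expect_equal(s$specificity, c(1, 1))

  b <- array(0L, dim(a))          # label 1 moved to a disjoint location
  b[7:10, 2:5, 2:5] <- 1L
  s2 <- overlap_scores(a * (a == 1L), b)
  expect_equal(s2$jaccard, 0)
  expect_equal(s2$dice, 0)
  expect_equal(s2$sensitivity, 0)

  # two 4x4x4 cubes overlapping in half their volume: J = 1/3, D = 1/2
  c1 <- array(0L, c(12, 8, 8)); c1[3:6, 3:6, 3:6] <- 1L
  c2 <- array(0L, c(12, 8, 8)); c2[5:8, 3:6, 3:6] <- 1L
  s3 <- overlap_scores(c1, c2)
  expect_equal(s3$jaccard, 1 / 3)
  expect_equal(s3$dice, 1 / 2)

  # label missing from one volume: defined scores, flagged
  s4 <- overlap_scores(a, array(0L, dim(a)))
  expect_true(all(s4$missing))
  expect_equal(s4$jaccard, c(0, 0))
})

test_that("Dice = 2J/(1+J) across labels of a random segmentation", {
  set.seed(3)
  a <- array(sample(0:4, 20^3, replace = TRUE), c(20, 20, 20))
  b <- array(sample(0:4, 20^3, replace = TRUE), c(20, 20, 20))
  s <- overlap_scores(a, b)
  expect_equal(s$dice, 2 * s$jaccard / (1 + s$jaccard), tolerance = 1e-12)
})

test_that("warp_quality_report bundles the metrics coherently", {
  g <- small_geom(shape = c(16, 16, 16))
  w <- make_diffeo_warp(g, c(12, 12, 12), amplitude = 3, seed = 4)
  labs <- array(0L, g$shape); labs[5:10, 5:10, 5:10] <- 1L
  rep <- warp_quality_report(w, labels_ref = labs, labels_mov = labs)
  expect_s3_class(rep, "warp_quality_report")
  expect_true(rep$jacdet$all_positive)
  expect_gte(rep$cvar$mean, 1)
  expect_true(all(rep$overlap$jaccard >= 0 & rep$overlap$jaccard <= 1))
  expect_equal(rep$overlap$dice,
               2 * rep$overlap$jaccard / (1 + rep$overlap$jaccard))
})
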
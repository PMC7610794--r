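# Cubic B-spline kernel and image interpolation.
#
# The same cubic B-spline beta3 serves two purposes: as the basis of the
# free-form deformation (R/warp.R) and, after prefiltering, as an
# interpolating model of the image intensities so that the moving-image
# spatial gradient needed by Gauss-Newton is the analytic derivative of a
# C^2 interpolant rather than a finite difference.

# beta3(t): cubic B-spline, support (-2, 2), partition of unity.
bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, 2 / 3 - at^2 + at^3 / 2,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

# d beta3 / dt
bspline3_d1 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, -2 * t + 1.5 * t * at,
         ifelse(at < 2, -sign(t) * (2 - at)^2 / 2, 0))
}

# Recursive prefilter turning samples into cubic B-spline interpolation
# coefficients (pole z = sqrt(3) - 2, gain 6), applied along `axis` with a
# truncated-mirror initialisation. arr must have >= 2 samples along axis.
prefilter_axis <- function(arr, axis) {
  z <- sqrt(3) - 2
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  dim(a) <- c(n, prod(d[-axis]))
  horizon <- ceiling(log(1e-15) / log(abs(z)))
  cp <- a
  if (horizon < n) {              # truncated mirror sum, error < 1e-15
    init <- a[1, ]
    zk <- 1
    for (k in 2:horizon) {
      zk <- zk * z
      init <- init + zk * a[k, ]
    }
  } else {                        # exact mirror-periodic initialisation
    mir <- c(1:n, (n - 1):2)
    init <- 0
    zk <- 1
    for (k in seq_along(mir)) {
      init <- init + zk * a[mir[k], ]
      zk <- zk * z
    }
    init <- init / (1 - z^(2 * n - 2))
  }
  cp[1, ] <- init
  for (k in 2:n) cp[k, ] <- a[k, ] + z * cp[k - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (k in (n - 1):1) cm[k, ] <- z * (cm[k + 1, ] - cp[k, ])
  out <- 6 * cm
  dim(out) <- c(n, d[perm[2]], d[perm[3]])
  aperm(out, order(perm))
}

# Interpolation coefficients for a whole volume.
bspline_prefilter <- function(data) {
  for (ax in 1:3) data <- prefilter_axis(data, ax)
  data
}

# Sample a (prefiltered, for method "cubic") volume at fractional 0-based
# voxel coordinates. vox: N x 3 matrix. Returns the sampled values and,
# optionally for cubic, the gradient with respect to the three voxel
# coordinate axes (per voxel unit; divide by voxel_size for mm).
# Out-of-field samples (outside the voxel-centre hull) get `fill`;
# boundary neighbours are border-replicated.
sample_volume_coefs <- function(coef, vox, fill = 0, gradient = FALSE) {
  d <- dim(coef)
  n <- nrow(vox)
  infield <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
             vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
             vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  i0 <- floor(vox)
  fr <- vox - i0
  w <- dw <- vector("list", 3L)
  for (a in 1:3) {
    tt <- outer(fr[, a], -(-1:2), `+`)   # distance to the 4 neighbours
    w[[a]] <- bspline3(tt)
    if (gradient) dw[[a]] <- bspline3_d1(tt)
  }
  idx <- vector("list", 3L)
  for (a in 1:3) {
    ks <- abs(outer(i0[, a], (-1):2, `+`))   # mirror about the first sample
    over <- ks > d[a] - 1                    # ... and about the last
    ks[over] <- 2 * (d[a] - 1) - ks[over]
    idx[[a]] <- pmin(pmax(ks, 0), d[a] - 1)
  }
  val <- numeric(n)
  gx <- gy <- gz <- if (gradient) numeric(n) else NULL
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    lin <- 1 + idx[[1]][, a] + d[1] * (idx[[2]][, b] + d[2] * idx[[3]][, cc])
    cv <- coef[lin]
    val <- val + w[[1]][, a] * w[[2]][, b] * w[[3]][, cc] * cv
    if (gradient) {
      gx <- gx + dw[[1]][, a] * w[[2]][, b] * w[[3]][, cc] * cv
      gy <- gy + w[[1]][, a] * dw[[2]][, b] * w[[3]][, cc] * cv
      gz <- gz + w[[1]][, a] * w[[2]][, b] * dw[[3]][, cc] * cv
    }
  }
  val[!infield] <- fill
  if (gradient) {
    gx[!infield] <- 0; gy[!infield] <- 0; gz[!infield] <- 0
    list(value = val, grad = cbind(gx, gy, gz), infield = infield)
  } else {
    list(value = val, infield = infield)
  }
}

# Trilinear sampling (no prefilter).
sample_volume_linear <- function(data, vox, fill = 0) {
  d <- dim(data)
  n <- nrow(vox)
  infield <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
             vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
             vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  i0 <- pmin(pmax(floor(vox), 0), rep(d - 2, each = n))
  fr <- vox - i0
  val <- numeric(n)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wt <- (if (a) fr[, 1] else 1 - fr[, 1]) *
          (if (b) fr[, 2] else 1 - fr[, 2]) *
          (if (cc) fr[, 3] else 1 - fr[, 3])
    lin <- 1 + (i0[, 1] + a) + d[1] * ((i0[, 2] + b) + d[2] * (i0[, 3] + cc))
    val <- val + wt * data[lin]
  }
  val[!infield] <- fill
  list(value = val, infield = infield)
}

# Nearest-neighbour sampling (labels).
sample_volume_nearest <- function(data, vox, fill = 0) {
  d <- dim(data)
  i <- round(vox)
  infield <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
             i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
             i[, 3] >= 0 & i[, 3] <= d[3] - 1
  i <- pmin(pmax(i, 0), rep(d - 1, each = nrow(vox)))
  val <- data[1 + i[, 1] + d[1] * (i[, 2] + d[2] * i[, 3])]
  val[!infield] <- fill
  list(value = val, infield = infield)
}
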
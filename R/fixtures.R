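# Synthetic phantoms and ground-truth diffeomorphic warps.
#
# Desk-scale stand-ins for brain-extracted structural images: a smooth
# low-frequency background plus ellipsoidal "structures" with flat
# interiors and smooth edges (emulating the relatively flat signal profile
# of white matter with contrast concentrated at tissue boundaries), plus a
# mid-frequency texture so that intensity gradients exist throughout the
# field of view. Every generator is a pure function of its seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' @param shape voxels per axis (default 64^3, desk scale).
#' @param voxel_size mm (default 2 mm isotropic).
#' @param n_blobs number of ellipsoidal structures (also labelled regions).
#' @param contrast intensity amplitude of the structures (background sits
#'   around 0.3-0.6; total intensities are of order 1).
#' @param edge_mm width of the smooth structure edge, mm.
#' @param seed integer; every derived quantity is reproducible from it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = c(2, 2, 2),
                         n_blobs = 6L, contrast = 0.5, edge_mm = 3,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_blobs >= 0L)
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 n_blobs = as.integer(n_blobs), contrast = contrast,
                 edge_mm = edge_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image and its label volume
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` ([image_volume()]), `labels` (integer array;
#'   0 background, 1..n_blobs the ellipsoid interiors, pairwise disjoint)
#'   and `blobs` (data frame of centres/semi-axes in mm, with the analytic
#'   ellipsoid volume).
#' @export
make_phantom <- function(spec) {
  with_seed(spec$seed, {
    geom <- vol_geometry(spec$shape, spec$voxel_size)
    ext <- (geom$shape - 1) * geom$voxel_size
    x <- lapply(1:3, function(a) axis_coords(geom, a))
    n <- prod(geom$shape)
    X <- rep(x[[1]], times = geom$shape[2] * geom$shape[3])
    Y <- rep(rep(x[[2]], each = geom$shape[1]), times = geom$shape[3])
    Z <- rep(x[[3]], each = geom$shape[1] * geom$shape[2])
    img <- rep(0.4, n)
    # broad background modulation
    for (k in 1:3) {
      c0 <- runif(3, 0.2, 0.8) * ext
      s0 <- runif(1, 0.25, 0.5) * mean(ext)
      img <- img + runif(1, -0.2, 0.2) *
        exp(-((X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2) / (2 * s0^2))
    }
    # mid-frequency texture: one bump per ~(24 mm)^3 so that intensity
    # gradients constrain the warp everywhere (as structural anatomy does);
    # each bump is evaluated only inside its +-3 sigma window
    img <- array(img, geom$shape)
    n_tex <- max(20L, round(prod(ext) / 24^3))
    for (k in seq_len(n_tex)) {
      c0 <- runif(3, 0.02, 0.98) * ext
      s0 <- runif(1, 4, 8)
      a0 <- runif(1, 0.1, 0.22) * sample(c(-1, 1), 1)
      lo <- pmax(1L, ceiling((c0 - 3 * s0) / geom$voxel_size) + 1L)
      hi <- pmin(geom$shape, floor((c0 + 3 * s0) / geom$voxel_size) + 1L)
      if (any(lo > hi)) next
      wx <- lapply(1:3, function(a)
        exp(-((lo[a]:hi[a] - 1) * geom$voxel_size[a] - c0[a])^2 /
              (2 * s0^2)))
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
        a0 * outer(outer(wx[[1]], wx[[2]]), wx[[3]])
    }
    img <- as.vector(img)
    labels <- integer(n)
    blobs <- NULL
    if (spec$n_blobs > 0) {
      centres <- matrix(NA_real_, 0, 3)
      axes <- matrix(NA_real_, 0, 3)
      margin <- 0.18 * ext
      tries <- 0L
      while (nrow(centres) < spec$n_blobs && tries < 2000L) {
        tries <- tries + 1L
        ax <- pmin(runif(3, 6, 13), 0.16 * ext)  # fit small fields of view
        ce <- margin + runif(3) * (ext - 2 * margin)
        ok <- TRUE
        if (nrow(centres) > 0) {
          dd <- sqrt(rowSums((centres - matrix(ce, nrow(centres), 3,
                                               byrow = TRUE))^2))
          ok <- all(dd > (apply(axes, 1, max) + max(ax) + 4))
        }
        if (ok) { centres <- rbind(centres, ce); axes <- rbind(axes, ax) }
      }
      if (nrow(centres) < spec$n_blobs)
        stop("make_phantom: could not place ", spec$n_blobs,
             " disjoint structures in this field of view")
      for (b in seq_len(nrow(centres))) {
        rho <- sqrt(((X - centres[b, 1]) / axes[b, 1])^2 +
                    ((Y - centres[b, 2]) / axes[b, 2])^2 +
                    ((Z - centres[b, 3]) / axes[b, 3])^2)
        amp <- spec$contrast * (if (b %% 2) 1 else -0.8)
        delta <- spec$edge_mm / mean(axes[b, ])
        img <- img + amp * stats::plogis((1 - rho) / (delta / 4))
        labels[rho <= 1] <- b
      }
      blobs <- data.frame(centres, axes)
      names(blobs) <- c("cx", "cy", "cz", "ax", "ay", "az")
      blobs$volume_mm3 <- 4 / 3 * pi * blobs$ax * blobs$ay * blobs$az
    }
    list(image = image_volume(array(img, geom$shape), geom$voxel_size,
                              geom$origin),
         labels = array(labels, geom$shape), blobs = blobs)
  })
}

#' Random diffeomorphic ground-truth warp
#'
#' Draws independent Gaussian coefficients on the knot lattice, smooths
#' them across the lattice so the warp is smooth at the knot scale, scales
#' to the requested maximum displacement, and verifies the minimum Jacobian
#' determinant exceeds 0.1 at the reference voxel centres. If the bound
#' fails, the lattice smoothing is increased and the draw repeated; an
#' error reports the best achieved bound if the requested amplitude cannot
#' be realised diffeomorphically.
#'
#' @param ref_geom [vol_geometry()] (or object carrying one).
#' @param knot_spacing knot spacing, mm.
#' @param amplitude target maximum displacement magnitude, mm (0 gives the
#'   identity warp).
#' @param seed integer.
#' @param min_det_bound required lower bound on the Jacobian determinant.
#' @return a [spline_warp()] with attributes `achieved_min_det` and
#'   `max_displacement`.
#' @export
make_diffeo_warp <- function(ref_geom, knot_spacing, amplitude, seed = 1L,
                             min_det_bound = 0.1) {
  stopifnot(amplitude >= 0)
  ref_geom <- geometry_of(ref_geom)
  if (amplitude == 0) {
    w <- identity_warp(ref_geom, knot_spacing)
    attr(w, "achieved_min_det") <- 1
    attr(w, "max_displacement") <- 0
    return(w)
  }
  with_seed(seed, {
    best_det <- -Inf
    for (attempt in 1:8) {
      sigma_knots <- 1 * 1.4^(attempt - 1)
      w <- identity_warp(ref_geom, knot_spacing)
      for (i in 1:3) {
        co <- array(stats::rnorm(prod(w$K)), w$K)
        for (a in 1:3)
          co <- apply_axis(co, gauss_band(w$K[a], sigma_knots), a)
        w$coeffs[[i]] <- co
      }
      d <- evaluate_displacement(w)
      mx <- max(sqrt(rowSums(matrix(d, ncol = 3)^2)))
      sc <- amplitude / mx
      for (i in 1:3) w$coeffs[[i]] <- w$coeffs[[i]] * sc
      md <- min(compute_jacobians(w, singvals = FALSE)$det)
      best_det <- max(best_det, md)
      if (md > min_det_bound) {
        attr(w, "achieved_min_det") <- md
        attr(w, "max_displacement") <- amplitude
        return(w)
      }
    }
    stop("make_diffeo_warp: amplitude ", amplitude,
         " mm not achievable with min |J| > ", min_det_bound,
         " (best achieved ", format(best_det), ")")
  })
}

#' Synthetic registration pair with known ground truth
#'
#' Builds a phantom, draws a ground-truth diffeomorphic warp `t*`, and
#' constructs the pair so that `t*` is exactly the spline warp a perfect
#' registration of (`ref`, `moving`) should recover: the reference is the
#' phantom resampled through `t*` (`ref(x) = phantom(t*(x))`), the moving
#' image is the phantom itself plus Gaussian noise, and the reference
#' labels are the phantom labels transported through `t*` by
#' nearest-neighbour. `snr` is the ratio of the phantom intensity range to
#' the noise standard deviation (`Inf` = noiseless).
#'
#' @param spec a [phantom_spec()].
#' @param knot_spacing,amplitude warp lattice (mm) and max displacement (mm)
#'   passed to [make_diffeo_warp()].
#' @param snr signal-to-noise ratio: sd of the phantom intensities divided
#'   by the noise sd.
#' @param seed integer (phantom, warp and noise are derived sub-seeds).
#' @return list: `ref`, `moving` ([image_volume()]s), `true_warp`
#'   ([spline_warp()]), `labels_ref`, `labels_mov` (integer arrays),
#'   `mask` (interior evaluation mask excluding the boundary belt where
#'   out-of-field effects live), `noise_sd`.
#' @export
make_pair <- function(spec, knot_spacing = 16, amplitude = 8, snr = 20,
                      seed = 1L) {
  ph <- make_phantom(spec)
  geom <- geometry_of(ph$image)
  true_warp <- make_diffeo_warp(geom, knot_spacing, amplitude,
                                seed = seed + 1000L)
  ref <- resample_image(ph$image, true_warp, "cubic", fill = 0)
  lab_mov <- image_volume(ph$labels + 0, geom$voxel_size, geom$origin)
  labels_ref <- resample_image(lab_mov, true_warp, "nearest", fill = 0)$data
  sig <- stats::sd(ph$image$data)
  noise_sd <- if (is.finite(snr) && snr > 0) sig / snr else 0
  moving <- ph$image
  if (noise_sd > 0)
    moving$data <- moving$data +
      with_seed(seed + 2000L,
                array(stats::rnorm(length(moving$data), sd = noise_sd),
                      dim(moving$data)))
  belt <- ceiling(amplitude / geom$voxel_size) + 2L
  mask <- array(FALSE, geom$shape)
  mask[(belt[1] + 1):(geom$shape[1] - belt[1]),
       (belt[2] + 1):(geom$shape[2] - belt[2]),
       (belt[3] + 1):(geom$shape[3] - belt[3])] <- TRUE
  list(ref = ref, moving = moving, true_warp = true_warp,
       labels_ref = labels_ref, labels_mov = ph$labels, mask = mask,
       noise_sd = noise_sd)
}
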
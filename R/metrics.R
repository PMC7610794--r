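#' Jacobian-determinant statistics of a warp
#'
#' Histograms and summary statistics of the per-voxel Jacobian determinants
#' within an optional mask: the standard audit of how aggressively a warp
#' compresses or expands tissue. Log statistics (including the 5th-95th
#' percentile range of `log |J|`) are only defined when all in-mask
#' determinants are positive; otherwise they are flagged and the non-log
#' statistics still reported.
#'
#' @param jac a `jacobian_field` from [compute_jacobians()].
#' @param mask optional logical/0-1 array on the same grid.
#' @param bins number of uniform histogram bins.
#' @return list with `summary` (min/max/mean/p5/p95 of det), `log_summary`
#'   (same for log det, plus `range_5_95`), `hist` and `log_hist`
#'   (bin edges + counts), `n`, `all_positive`.
#' @export
jacdet_stats <- function(jac, mask = NULL, bins = 200L) {
  det <- as.vector(jac$det)
  if (!is.null(mask)) det <- det[as.logical(mask)]
  n <- length(det)
  if (n == 0) stop("jacdet_stats: empty mask")
  qs <- stats::quantile(det, c(0.05, 0.95), names = FALSE, type = 7)
  summary <- c(min = min(det), max = max(det), mean = mean(det),
               p5 = qs[1], p95 = qs[2])
  edges <- seq(min(det), max(det), length.out = bins + 1L)
  if (edges[1] == edges[bins + 1L])   # constant field (e.g. identity warp)
    edges <- seq(edges[1] - 0.5, edges[1] + 0.5, length.out = bins + 1L)
  h <- graphics::hist(det, breaks = edges, plot = FALSE)
  all_pos <- all(det > 0)
  log_summary <- NULL; log_hist <- NULL
  if (all_pos) {
    ld <- log(det)
    lq <- stats::quantile(ld, c(0.05, 0.95), names = FALSE, type = 7)
    log_summary <- c(min = min(ld), max = max(ld), mean = mean(ld),
                     p5 = lq[1], p95 = lq[2], range_5_95 = lq[2] - lq[1])
    r <- max(abs(ld), 1e-12)
    ledges <- seq(-r, r, length.out = bins + 1L)
    log_hist <- graphics::hist(ld, breaks = ledges, plot = FALSE)
    log_hist <- list(edges = ledges, counts = log_hist$counts)
  }
  list(summary = summary, log_summary = log_summary,
       hist = list(edges = edges, counts = h$counts),
       log_hist = log_hist, n = n, all_positive = all_pos)
}

#' Cube-volume aspect ratio map
#'
#' CVAR quantifies local shape (as opposed to volume) distortion: the cube
#' root of the ratio between the volume of the smallest cube enclosing the
#' image of a deformed unit cube and its actual volume. For the local
#' linear map with singular values `s1 >= s2 >= s3 > 0` this is
#' `(s1^3 / (s1 s2 s3))^(1/3) = s1 / |det J|^(1/3)`: 1 for any rigid motion
#' or isotropic scaling, growing with anisotropy.
#'
#' @inheritParams jacdet_stats
#' @return list with `map` (3D array, NA where det <= 0), `mean` (over
#'   in-mask voxels with positive determinant), `n_invalid`.
#' @export
cvar_map <- function(jac, mask = NULL) {
  if (is.null(jac$singvals))
    stop("cvar_map: jacobian field lacks singular values")
  det <- as.vector(jac$det)
  cv <- jac$singvals[, 1] / pmax(det, 0)^(1 / 3)
  cv[det <= 0] <- NA_real_
  map <- array(cv, dim(jac$det))
  sel <- if (is.null(mask)) !is.na(cv) else as.logical(mask) & !is.na(cv)
  list(map = map, mean = mean(cv[sel]),
       n_invalid = sum(det <= 0 & (if (is.null(mask)) TRUE else as.logical(mask))))
}

#' Label overlap scores
#'
#' Per-label Jaccard, Dice, sensitivity and specificity between a reference
#' segmentation and a warped segmentation on the same grid, from the 2x2
#' contingency of `{ref == l}` against `{warped == l}`. Label 0 is
#' background and not scored. A label present in only one volume gets
#' defined scores (Jaccard 0) and is flagged.
#'
#' @param labels_ref,labels_warped integer label arrays (or
#'   [image_volume()]s) on the same grid.
#' @return data frame with one row per label: `label`, `jaccard`, `dice`,
#'   `sensitivity`, `specificity`, `n_ref`, `n_warped`, `missing`.
#' @export
overlap_scores <- function(labels_ref, labels_warped) {
  a <- if (inherits(labels_ref, "image_volume")) labels_ref$data else labels_ref
  b <- if (inherits(labels_warped, "image_volume")) labels_warped$data else labels_warped
  if (!all(dim(a) == dim(b))) stop("overlap_scores: geometry mismatch")
  labs <- sort(setdiff(unique(c(as.vector(a), as.vector(b))), 0))
  n <- length(a)
  out <- lapply(labs, function(l) {
    ra <- a == l; rb <- b == l
    tp <- sum(ra & rb); fp <- sum(!ra & rb); fn <- sum(ra & !rb)
    tn <- n - tp - fp - fn
    data.frame(label = l,
               jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
               dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               n_ref = sum(ra), n_warped = sum(rb),
               missing = sum(ra) == 0 || sum(rb) == 0)
  })
  do.call(rbind, out)
}

#' Warp quality report
#'
#' Bundles the warp-audit metrics for a fitted or supplied warp: Jacobian
#' determinant histogram and summary (log and non-log), CVAR map and mean,
#' and, when label volumes are given, per-label overlap scores after
#' transporting the moving labels through the warp by nearest-neighbour
#' resampling.
#'
#' @param warp a [spline_warp()].
#' @param geom evaluation grid (default: the warp's reference grid).
#' @param mask optional logical array (e.g. a brain mask): statistics are
#'   restricted to it.
#' @param labels_ref reference segmentation ([image_volume()] or array).
#' @param labels_mov moving segmentation, transported through the warp
#'   before scoring.
#' @return list of class `warp_quality_report`.
#' @export
warp_quality_report <- function(warp, geom = warp$ref_geom, mask = NULL,
                                labels_ref = NULL, labels_mov = NULL) {
  geom <- geometry_of(geom)
  jac <- compute_jacobians(warp, geom)
  jd <- jacdet_stats(jac, mask)
  cv <- cvar_map(jac, mask)
  overlap <- NULL
  if (!is.null(labels_ref) && !is.null(labels_mov)) {
    lm <- if (inherits(labels_mov, "image_volume")) labels_mov else
      image_volume(labels_mov, geom$voxel_size, geom$origin)
    warped <- resample_image(lm, warp, "nearest", fill = 0, geom = geom)
    lr <- if (inherits(labels_ref, "image_volume")) labels_ref$data else labels_ref
    overlap <- overlap_scores(lr, warped$data)
  }
  structure(list(jacdet = jd, cvar = list(mean = cv$mean,
                                          n_invalid = cv$n_invalid),
                 cvar_map = cv$map, overlap = overlap,
                 min_det = jd$summary[["min"]], geom = geom),
            class = "warp_quality_report")
}

#' @export
print.warp_quality_report <- function(x, ...) {
  s <- x$jacdet$summary
  cat("<warp_quality_report>\n")
  cat(sprintf("  |J|: min %.3f mean %.3f max %.3f (5th-95th %.3f-%.3f)\n",
              s[["min"]], s[["mean"]], s[["max"]], s[["p5"]], s[["p95"]]))
  if (!is.null(x$jacdet$log_summary))
    cat(sprintf("  log|J| 5th-95th range: %.4f\n",
                x$jacdet$log_summary[["range_5_95"]]))
  else cat("  log|J| stats undefined (non-positive determinants present)\n")
  cat(sprintf("  mean CVAR: %.4f\n", x$cvar$mean))
  if (!is.null(x$overlap)) {
    cat(sprintf("  overlap over %d labels: mean Jaccard %.3f, mean Dice %.3f\n",
                nrow(x$overlap), mean(x$overlap$jaccard),
                mean(x$overlap$dice)))
  }
  invisible(x)
}
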
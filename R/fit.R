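#' Fit a nonlinear registration
#'
#' The front-end of the package: registers `moving` to `ref` with the
#' multi-level Levenberg-damped Gauss-Newton scheme of
#' [run_registration()] and returns a fitted-model object carrying the
#' estimated [spline_warp()], the optimisation trace and a warp-quality
#' audit, with the usual methods (`print`, `summary`, `coef`, `predict`,
#' `residuals`, `plot`).
#'
#' @param ref reference [image_volume()] (the fixed image; the warp lives
#'   on its grid).
#' @param moving moving [image_volume()] to be deformed onto `ref`.
#' @param config a [registration_config()].
#' @param mask optional logical array on the reference grid restricting
#'   the similarity term.
#' @param report compute a [warp_quality_report()] on the full reference
#'   grid after fitting.
#' @return object of class `warpreg_fit`.
#' @examples
#' \donttest{
#' pair <- make_pair(phantom_spec(shape = c(32, 32, 32), seed = 1),
#'                   knot_spacing = 16, amplitude = 4, snr = 20, seed = 1)
#' fit <- register_volumes(pair$ref, pair$moving,
#'                         registration_config(levels = data.frame(
#'                           subsample = 2, fwhm_vox = 2, knot_vox = 8,
#'                           max_iter = 10)))
#' summary(fit)
#' }
#' @export
register_volumes <- function(ref, moving, config = registration_config(),
                             mask = NULL, report = TRUE) {
  warped0 <- moving
  msq0 <- msq_value(ref, warped0, mask)
  res <- run_registration(ref, moving, config, mask)
  warped <- resample_image(moving, res$warp, "cubic", geom = geometry_of(ref))
  msq1 <- msq_value(ref, warped, mask)
  rep <- if (report)
    warp_quality_report(res$warp, geometry_of(ref), mask = mask)
  structure(list(warp = res$warp, log = res$log, converged = res$converged,
                 final = res$final, config = config,
                 ref = ref, moving = moving, mask = mask,
                 msq_initial = msq0, msq_final = msq1,
                 report = rep, call = match.call()),
            class = "warpreg_fit")
}

#' @export
print.warpreg_fit <- function(x, ...) {
  cat("Nonlinear B-spline registration (", x$config$penalty,
      " penalty, lambda = ", format(x$config$lambda), ")\n", sep = "")
  cat("  levels: ", nrow(x$config$levels), "; iterations: ",
      nrow(x$log), "; converged: ",
      paste(ifelse(x$converged, "yes", "no"), collapse = "/"), "\n", sep = "")
  cat("  MSQ ", format(x$msq_initial, digits = 4), " -> ",
      format(x$msq_final, digits = 4), "  (",
      sprintf("%.1f%%", 100 * (1 - x$msq_final / x$msq_initial)),
      " reduction)\n", sep = "")
  if (!is.null(x$report))
    cat("  min |J| ", format(x$report$min_det, digits = 4),
        ", mean CVAR ", format(x$report$cvar$mean, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.warpreg_fit <- function(object, ...) {
  disp <- evaluate_displacement(object$warp)
  mag <- sqrt(rowSums(matrix(disp, ncol = 3)^2))
  out <- list(fit = object,
              displacement = c(mean = mean(mag), max = max(mag)),
              n_par = 3 * n_coef(object$warp))
  class(out) <- "summary.warpreg_fit"
  out
}

#' @export
print.summary.warpreg_fit <- function(x, ...) {
  print(x$fit)
  cat("  parameters: ", x$n_par, " spline coefficients\n", sep = "")
  cat("  displacement: mean ", format(x$displacement[["mean"]], digits = 4),
      " mm, max ", format(x$displacement[["max"]], digits = 4), " mm\n",
      sep = "")
  if (!is.null(x$fit$report) && !is.null(x$fit$report$jacdet$log_summary))
    cat("  log|J| 5th-95th range: ",
        format(x$fit$report$jacdet$log_summary[["range_5_95"]], digits = 4),
        "\n", sep = "")
  invisible(x)
}

#' @export
coef.warpreg_fit <- function(object, ...) warp_par(object$warp)

#' Apply a fitted warp
#'
#' `predict` resamples a volume through the fitted warp (by default the
#' moving image onto the reference grid), or, with `what = "displacement"`,
#' returns the dense displacement field.
#'
#' @param object a `warpreg_fit`.
#' @param newdata an [image_volume()] to resample (default: the moving
#'   image of the fit).
#' @param what `"image"` or `"displacement"`.
#' @param interpolation passed to [resample_image()].
#' @param ... unused.
#' @export
predict.warpreg_fit <- function(object, newdata = NULL,
                                what = c("image", "displacement"),
                                interpolation = "cubic", ...) {
  what <- match.arg(what)
  if (what == "displacement")
    return(evaluate_displacement(object$warp))
  if (is.null(newdata)) newdata <- object$moving
  resample_image(newdata, object$warp, interpolation,
                 geom = geometry_of(object$ref))
}

#' @export
residuals.warpreg_fit <- function(object, ...) {
  warped <- predict(object)
  object$ref$data - warped$data
}

#' Diagnostic plots for a registration fit
#'
#' Panels: the optimisation cost trace (log scale, level boundaries
#' marked), the in-brain Jacobian-determinant histogram, and a mid-axial
#' slice of the residual image.
#'
#' @param x a `warpreg_fit`.
#' @param which subset of `1:3`.
#' @param ... unused.
#' @export
plot.warpreg_fit <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(seq_len(nrow(x$log)), x$log$cost, type = "b", log = "y",
                   xlab = "accepted iteration", ylab = "total cost",
                   main = "cost trace", pch = 20)
    lv <- cumsum(rle(x$log$level)$lengths)
    graphics::abline(v = lv[-length(lv)] + 0.5, lty = 3)
  }
  if (2 %in% which && !is.null(x$report)) {
    h <- x$report$jacdet$hist
    graphics::plot(utils::head(h$edges, -1), h$counts, type = "h",
                   xlab = "|J|", ylab = "voxels",
                   main = "Jacobian determinants")
    graphics::abline(v = 1, lty = 2)
  }
  if (3 %in% which) {
    r <- residuals(x)
    k <- ceiling(dim(r)[3] / 2)
    graphics::image(r[, , k], main = "residual (mid slice)",
                    col = grDevices::hcl.colors(64, "Blue-Red"),
                    useRaster = TRUE)
  }
  invisible(x)
}
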
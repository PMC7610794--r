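#' Registration configuration
#'
#' Settings for the multi-smoothing, multi-resolution registration. Each
#' pyramid level smooths both images with a Gaussian (`fwhm_vox`, in units
#' of the reference voxel size), subsamples the reference sampling grid
#' (`subsample`), and optimises spline coefficients at `knot_vox` reference
#' voxels of knot spacing. Knot spacings are non-increasing across levels.
#'
#' @param levels data frame with columns `subsample`, `fwhm_vox`,
#'   `knot_vox`, `max_iter`; one row per pyramid level (default: a
#'   three-level desk-scale pyramid, 4/2/2 subsampling, 4/2/1 voxel FWHM,
#'   8/8/4 voxel knots).
#' @param penalty regulariser: `"spred"`, `"jacdet"` or `"rigidity"`.
#' @param lambda trade-off weight multiplying the regulariser against the
#'   sum-of-squares similarity. The useful scale depends on the intensity
#'   units; the default is calibrated for intensities of order 1 (see the
#'   methods vignette and [calibrate_weight()]).
#' @param optimiser `"levenberg"` (damped Gauss-Newton) or `"mm"`
#'   (majorise-minimise diagonal surrogate).
#' @param tol per-level convergence tolerance on the relative cost decrease.
#' @param guard reject any step producing a non-positive Jacobian
#'   determinant (the diffeomorphism guard). Disable only for experiments.
#' @param lambda_init_scale,lambda_up,lambda_down Levenberg damping
#'   schedule: initial `lambda_L = lambda_init_scale * mean(diag(H))`,
#'   multiplied by `lambda_up` on rejection, divided by `lambda_down` on
#'   acceptance.
#' @param lambda_ceiling,max_rejects give up on a level when the damping
#'   exceeds the ceiling or this many consecutive rejections occur.
#' @param direct_solve_max use a direct sparse solve for systems up to this
#'   many parameters; larger systems use preconditioned conjugate gradients.
#' @param cg_tol,cg_maxit relative residual tolerance and iteration cap of
#'   the conjugate-gradient solver.
#' @param verbose print per-iteration progress.
#' @return list of class `registration_config`.
#' @export
registration_config <- function(levels = NULL,
                                penalty = c("spred", "jacdet", "rigidity"),
                                lambda = 3e-5,
                                optimiser = c("levenberg", "mm"),
                                tol = 1e-6, guard = TRUE,
                                lambda_init_scale = 5e-2,
                                lambda_up = 10, lambda_down = 5,
                                lambda_ceiling = 1e12, max_rejects = 12,
                                direct_solve_max = 3000,
                                cg_tol = 1e-8, cg_maxit = 600,
                                verbose = FALSE) {
  if (is.null(levels))
    levels <- data.frame(subsample = c(4, 2, 2),
                         fwhm_vox = c(4, 2, 1),
                         knot_vox = c(8, 8, 4),
                         max_iter = c(20, 12, 8))
  stopifnot(all(c("subsample", "fwhm_vox", "knot_vox", "max_iter") %in%
                names(levels)))
  if (any(diff(levels$knot_vox) > 0))
    stop("knot spacings must be non-increasing across levels")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(levels = levels, penalty = match.arg(penalty),
                 lambda = lambda, optimiser = match.arg(optimiser),
                 tol = tol, guard = guard,
                 lambda_init_scale = lambda_init_scale,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 lambda_ceiling = lambda_ceiling, max_rejects = max_rejects,
                 direct_solve_max = direct_solve_max,
                 cg_tol = cg_tol, cg_maxit = cg_maxit, verbose = verbose),
            class = "registration_config")
}

#' Levenberg-damped Gauss-Newton step
#'
#' Solves `(H + lambda_L I) delta = -grad` for the coefficient update.
#' Uses a direct sparse solve for small systems and Jacobi-preconditioned
#' conjugate gradients (relative residual `cg_tol`) for large ones.
#'
#' @param grad gradient vector (length 3M).
#' @param hessian symmetric PSD matrix (sparse or dense), 3M x 3M.
#' @param lambda_L damping scalar >= 0.
#' @param direct_max,cg_tol,cg_maxit solver controls.
#' @return the update `delta` (numeric).
#' @export
levenberg_step <- function(grad, hessian, lambda_L, direct_max = 3000,
                           cg_tol = 1e-8, cg_maxit = 600) {
  if (lambda_L < 0) stop("lambda_L must be >= 0")
  n <- length(grad)
  if (n <= direct_max) {
    A <- hessian + lambda_L * Matrix::Diagonal(n)
    d <- tryCatch(as.numeric(Matrix::solve(A, -grad)),
                  error = function(e)
                    stop("singular Levenberg system; increase lambda_L",
                         call. = FALSE))
    return(d)
  }
  dg <- Matrix::diag(hessian) + lambda_L
  dg[dg <= 0] <- max(dg[dg > 0], 1)
  cg_solve(function(x) as.numeric(hessian %*% x) + lambda_L * x,
           -grad, precond = 1 / dg, tol = cg_tol, maxit = cg_maxit)
}

# Jacobi-preconditioned conjugate gradients for SPD systems.
cg_solve <- function(amul, b, precond, tol = 1e-8, maxit = 600) {
  x <- numeric(length(b))
  r <- b
  z <- precond * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- amul(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bn) break
    z <- precond * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' Majorise-minimise diagonal surrogate
#'
#' Replaces the Gauss-Newton Hessian by the diagonal matrix whose i-th
#' entry is the sum of absolute values of the i-th column of `H`. By
#' Gershgorin's theorem `D - H` is positive semidefinite, so minimising the
#' diagonal surrogate still guarantees descent on the quadratic model.
#'
#' @param hessian symmetric matrix (sparse or dense).
#' @return [Matrix::Diagonal()] matrix of the absolute column sums.
#' @export
mm_diagonal <- function(hessian) {
  Matrix::Diagonal(x = as.numeric(Matrix::colSums(abs(hessian))))
}

# --- registration driver ---------------------------------------------------

#' Run a multi-level registration
#'
#' Registers `moving` to `ref` (both assumed affine-aligned in the same
#' world frame): per pyramid level, both images are Gaussian-smoothed, the
#' reference sampling grid is subsampled, the warp is carried over from the
#' previous level, and Levenberg-damped Gauss-Newton iterations minimise
#' `0.5 sum r^2 + lambda * penalty`. A candidate step is accepted only if it
#' decreases the total cost and (with the guard on) keeps every Jacobian
#' determinant positive; otherwise the damping is increased and the step
#' re-solved. Non-finite penalties (folded candidate warps) count as
#' rejections.
#'
#' Most users should call [register_volumes()], which wraps this and
#' returns a fitted-model object with methods.
#'
#' @param ref,moving [image_volume()]s.
#' @param config a [registration_config()].
#' @param mask optional logical array on the reference grid restricting the
#'   similarity domain.
#' @return list with the final `warp`, the per-iteration `log` data frame,
#'   `converged` flags per level, and the final cost breakdown.
#' @export
run_registration <- function(ref, moving, config = registration_config(),
                             mask = NULL) {
  stopifnot(inherits(ref, "image_volume"), inherits(moving, "image_volume"))
  if (any(!is.finite(ref$data)) || any(!is.finite(moving$data)))
    stop("non-finite input intensities")
  lv <- config$levels
  warp <- NULL
  log_rows <- list()
  converged <- logical(nrow(lv))
  for (l in seq_len(nrow(lv))) {
    sub <- lv$subsample[l]
    fwhm <- lv$fwhm_vox[l] * ref$voxel_size
    knot <- lv$knot_vox[l] * ref$voxel_size
    ref_l <- subsample_volume(smooth_volume(ref, fwhm), sub)
    mov_l <- smooth_volume(moving, fwhm)
    geom_l <- geometry_of(ref_l)
    mask_l <- if (!is.null(mask)) {
      d <- dim(mask)
      idx <- lapply(1:3, function(a) seq(1L, d[a], by = sub))
      mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    warp <- if (is.null(warp)) {
      identity_warp(geometry_of(ref), knot)
    } else if (all(abs(warp$knot_spacing - knot) < 1e-9)) {
      warp
    } else {
      refine_warp(warp, knot, geom_l)
    }
    res <- optimise_level(ref_l, mov_l, warp, config, mask_l,
                          max_iter = lv$max_iter[l], level = l)
    warp <- res$warp
    converged[l] <- res$converged
    log_rows[[l]] <- res$log
  }
  log <- do.call(rbind, log_rows)
  list(warp = warp, log = log, converged = converged,
       final = res$final, config = config)
}

# Single-level Levenberg (or MM) optimisation.
optimise_level <- function(ref_l, mov_l, warp, config, mask_l, max_iter,
                           level = 1L) {
  geom_l <- geometry_of(ref_l)
  type <- config$penalty
  lam <- config$lambda
  kb <- warp_kron_bases(warp, geom_l)
  cache <- list(mov_coefs = bspline_prefilter(mov_l$data), kb = kb["K0"])
  names(cache$kb) <- "K0"

  eval_point <- function(w, derivatives) {
    reg <- if (lam > 0)
      warp_penalty(w, type, geom_l, derivatives, kb = kb)
    else NULL
    min_det <- if (!is.null(reg) && !is.na(reg$min_det)) reg$min_det else
      min(compute_jacobians(w, geom_l, singvals = FALSE)$det)
    if (!is.null(reg) && !reg$finite)
      return(list(ok = FALSE, cost = Inf, min_det = min_det))
    sim <- msq_grad_hessian(ref_l, mov_l, w, mask_l, derivatives, cache)
    regv <- if (is.null(reg)) 0 else reg$value
    list(ok = TRUE, cost = sim$value + lam * regv, sim = sim, reg = reg,
         min_det = min_det)
  }

  cur <- eval_point(warp, "hessian")
  if (!cur$ok)
    stop("initial warp is non-diffeomorphic at level ", level)
  lamL <- NA_real_
  rows <- list()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- cur$sim$gradient
    H <- cur$sim$hessian
    if (lam > 0) {
      g <- g + lam * cur$reg$gradient
      H <- H + lam * cur$reg$hessian
    }
    if (sqrt(sum(g^2)) <= 1e-10 * max(1, abs(cur$cost))) {
      converged <- TRUE   # already at a stationary point (e.g. mov == ref)
      break
    }
    if (is.na(lamL))
      lamL <- config$lambda_init_scale * mean(Matrix::diag(H))
    if (config$optimiser == "mm") H <- mm_diagonal(H)
    accepted <- FALSE
    rejects <- 0L
    repeat {
      delta <- levenberg_step(g, H, lamL, config$direct_solve_max,
                              config$cg_tol, config$cg_maxit)
      cand <- warp_set_par(warp, warp_par(warp) + delta)
      ev <- eval_point(cand, "none")
      ok_det <- !config$guard || ev$min_det > 0
      if (ev$ok && ev$cost < cur$cost && ok_det) {
        accepted <- TRUE
        break
      }
      rejects <- rejects + 1L
      lamL <- lamL * config$lambda_up
      if (lamL > config$lambda_ceiling || rejects >= config$max_rejects)
        break
    }
    if (!accepted) {
      warning("level ", level, ": no acceptable step after ", rejects,
              " rejections (lambda_L = ", format(lamL), ")")
      break
    }
    rel_drop <- (cur$cost - ev$cost) / max(abs(cur$cost), 1e-300)
    warp <- cand
    cur <- eval_point(warp, "hessian")
    lamL <- lamL / config$lambda_down
    rows[[it]] <- data.frame(level = level, iter = it, cost = cur$cost,
                             sim = cur$sim$value,
                             reg = if (lam > 0) cur$reg$value else 0,
                             lambda_L = lamL, min_det = cur$min_det,
                             rejects = rejects)
    if (config$verbose)
      message(sprintf("L%d it%02d cost %.6g (sim %.4g reg %.4g) minDet %.3f lamL %.2g rej %d",
                      level, it, cur$cost, cur$sim$value, rows[[it]]$reg,
                      cur$min_det, lamL, rejects))
    if (rel_drop < config$tol) { converged <- TRUE; break }
  }
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(0), iter = integer(0), cost = numeric(0),
               sim = numeric(0), reg = numeric(0), lambda_L = numeric(0),
               min_det = numeric(0), rejects = integer(0))
  list(warp = warp, log = log, converged = converged,
       final = list(cost = cur$cost, sim = cur$sim$value,
                    reg = if (lam > 0) cur$reg$value else 0,
                    min_det = cur$min_det))
}

#' Calibrate the regularisation weight to a target similarity
#'
#' Comparing regularisers is only meaningful at matched data consistency:
#' this helper searches (log-space secant on `lambda`) for the weight at
#' which a registration with penalty `type` reaches a given final
#' mean-squares value on a fixture pair, the calibration protocol used when
#' contrasting penalty behaviours.
#'
#' @param ref,moving the image pair.
#' @param type penalty to calibrate.
#' @param target_msq final in-mask [msq_value()] to match.
#' @param config base [registration_config()] (its `penalty`/`lambda` are
#'   overridden).
#' @param mask optional similarity mask.
#' @param lambda0 starting weight.
#' @param rel_tol acceptable relative mismatch in final MSQ.
#' @param max_eval registration budget.
#' @return list with `lambda`, the achieved `msq`, and the final `fit`.
#' @export
calibrate_weight <- function(ref, moving, type, target_msq,
                             config = registration_config(), mask = NULL,
                             lambda0 = 0.01, rel_tol = 0.1, max_eval = 6L) {
  cfg <- config
  cfg$penalty <- type
  run_at <- function(lam) {
    cfg$lambda <- lam
    fit <- run_registration(ref, moving, cfg, mask)
    warped <- resample_image(moving, fit$warp, "cubic", geom = geometry_of(ref))
    list(fit = fit, msq = msq_value(ref, warped, mask))
  }
  l1 <- log(lambda0)
  r1 <- run_at(exp(l1))
  best <- list(lambda = exp(l1), msq = r1$msq, fit = r1$fit)
  if (abs(r1$msq - target_msq) / target_msq <= rel_tol) return(best)
  # MSQ increases with lambda: bracket by stepping in the needed direction
  l2 <- if (r1$msq > target_msq) l1 - log(10) else l1 + log(10)
  r2 <- run_at(exp(l2))
  for (k in seq_len(max_eval - 2L)) {
    if (abs(r2$msq - target_msq) / target_msq <= rel_tol)
      return(list(lambda = exp(l2), msq = r2$msq, fit = r2$fit))
    # secant in log(msq) vs log(lambda)
    s <- (log(r2$msq) - log(r1$msq)) / (l2 - l1)
    l3 <- if (abs(s) < 1e-12) (l1 + l2) / 2 else
      l2 + (log(target_msq) - log(r2$msq)) / s
    l3 <- min(max(l3, min(l1, l2) - log(100)), max(l1, l2) + log(100))
    l1 <- l2; r1 <- r2
    l2 <- l3; r2 <- run_at(exp(l2))
  }
  list(lambda = exp(l2), msq = r2$msq, fit = r2$fit)
}
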
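#' Force-reliability weighting
#'
#' Weight applied to each experimental force value in the calibration
#' objective: 2 for forces at or above 100 mN (most reliable), 1 between
#' 30 and 100 mN, 0 below 30 mN (noise-dominated readings are ignored).
#'
#' @param force Experimental force values, mN.
#' @return Integer weights in `{0, 1, 2}`, same length as `force`.
#' @examples
#' force_weight(c(150, 100, 50, 30, 10))
#' @export
force_weight <- function(force) {
  stopifnot(is.numeric(force))
  ifelse(force >= 100, 2L, ifelse(force >= 30, 1L, 0L))
}

#' Calibration configuration
#'
#' Bounds, initial guess and optimizer settings for the inverse
#' identification. Defaults: `C10` start 1.0 in `[0.01, 10]` kPa, `k1`
#' start 0.1 in `[0, 10]` kPa, `k2` start 1.0 in `[0, 10]`, `kappa`
#' start 0 in `[0, 0.33]`; three starting points (the fixed initial
#' guess plus two uniform draws within bounds).
#'
#' @param initial Named numeric vector `(C10, k1, k2, kappa)`.
#' @param lower,upper Named bound vectors.
#' @param n_starts Number of multistart points (>= 1).
#' @param seed Seed for the random starts.
#' @param ftol,ptol Convergence tolerances passed to the trust-region
#'   least-squares solver.
#' @param max_iter Iteration cap per start.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(
    initial = c(C10 = 1.0, k1 = 0.1, k2 = 1.0, kappa = 0.0),
    lower = c(C10 = 0.01, k1 = 0.0, k2 = 0.0, kappa = 0.0),
    upper = c(C10 = 10.0, k1 = 10.0, k2 = 10.0, kappa = 0.33),
    n_starts = 3L, seed = 1L, ftol = 1e-8, ptol = 1e-8, max_iter = 200L) {
  nm <- c("C10", "k1", "k2", "kappa")
  stopifnot(all(nm %in% names(initial)), all(nm %in% names(lower)),
            all(nm %in% names(upper)), n_starts >= 1)
  initial <- initial[nm]; lower <- lower[nm]; upper <- upper[nm]
  if (any(initial < lower | initial > upper))
    stop("initial guess must lie within the bounds")
  if (upper[["kappa"]] > 1 / 3) upper[["kappa"]] <- 1 / 3 - 1e-9
  structure(list(initial = initial, lower = lower, upper = upper,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 ftol = ftol, ptol = ptol, max_iter = as.integer(max_iter)),
            class = "calibration_config")
}

#' Multistart initial points
#'
#' The first point is the configured initial guess; the remaining
#' `n_starts - 1` are drawn uniformly within the bounds under the
#' configured seed.
#'
#' @param config A [calibration_config()].
#' @param seed Optional seed override.
#' @return A list of named parameter vectors.
#' @export
multistart_points <- function(config, seed = NULL) {
  stopifnot(inherits(config, "calibration_config"))
  if (is.null(seed)) seed <- config$seed
  pts <- list(config$initial)
  if (config$n_starts > 1) {
    extra <- withr_seed(seed, {
      m <- matrix(stats::runif(4 * (config$n_starts - 1L)),
                  ncol = 4, byrow = TRUE)
      sweep(sweep(m, 2, config$upper - config$lower, "*"), 2, config$lower, "+")
    })
    for (i in seq_len(nrow(extra))) {
      v <- extra[i, ]
      names(v) <- names(config$initial)
      pts[[i + 1L]] <- v
    }
  }
  pts
}

# resolve the predictor argument into function(theta4, thickness) -> forces,
# with an analytic parameter Jacobian where one is available
resolve_predictor <- function(predictor, geom, protocol, form) {
  if (inherits(predictor, "surrogate_model")) {
    list(fn = function(theta, t)
      suppressWarnings(predict_forces(predictor, theta, t)),
      jac = function(theta, t) surrogate_force_jac(predictor, theta, t),
      label = "surrogate", space = predictor$space)
  } else if (is.function(predictor)) {
    list(fn = predictor, jac = NULL, label = "custom", space = NULL)
  } else if (identical(predictor, "homogeneous")) {
    if (form != "standard") {
      list(fn = function(theta, t)
        forward_map_homogeneous(theta, t, geom, protocol, form),
        jac = NULL, label = "homogeneous", space = NULL)
    } else {
      list(fn = function(theta, t)
        forward_map_homogeneous(theta, t, geom, protocol, form),
        jac = function(theta, t)
          forward_jac_homogeneous(theta, t, geom, protocol),
        label = "homogeneous", space = NULL)
    }
  } else stop("predictor must be a surrogate_model, a function, or \"homogeneous\"")
}

#' Weighted least-squares calibration objective
#'
#' \eqn{\varphi = \sum_i [W(F_{exp,i}) (F_{exp,i} - F_{num,i})]^2},
#' pooling both loading directions; weights depend on the experimental
#' forces only.
#'
#' @param params [hgo_params()] or length-4 vector.
#' @param exp_forces Experimental force vector (mN), or a [force_curve()].
#' @param predictor `"homogeneous"`, a `surrogate_model`, or a function
#'   `(theta4, thickness) -> forces`.
#' @param thickness Sample thickness, mm.
#' @param geom,protocol Used by the `"homogeneous"` predictor.
#' @param form Energy form for the `"homogeneous"` predictor.
#' @return The scalar objective value.
#' @export
calibration_objective <- function(params, exp_forces, predictor = "homogeneous",
                                  thickness = 2.0, geom = rake_geometry(),
                                  protocol = loading_protocol(),
                                  form = "standard") {
  if (inherits(exp_forces, "force_curve")) exp_forces <- force_vector(exp_forces)
  pr <- resolve_predictor(predictor, geom, protocol, form)
  w <- force_weight(exp_forces)
  r <- tryCatch(w * (exp_forces - pr$fn(as.numeric(unlist(as_hgo_params(params)[1:4])),
                                        thickness)),
                error = function(e) NULL)
  if (is.null(r) || any(!is.finite(r))) return(1e30)
  sum(r^2)
}

#' Calibrate HGO parameters from a measured force curve
#'
#' Bounded weighted nonlinear least squares: the residual vector
#' `W(F_exp) * (F_exp - F_model(theta))` is minimized with a
#' Levenberg--Marquardt trust-region solver under box bounds, restarted
#' from each multistart point; the best converged start wins (ties go to
#' the lowest start index). With a surrogate predictor the bounds are
#' intersected with the surrogate's training space.
#'
#' @param exp_curve A [force_curve()] or plain force vector (mN).
#' @param thickness Sample thickness, mm.
#' @param predictor `"homogeneous"` (default), a `surrogate_model`, or a
#'   function `(theta4, thickness) -> forces`.
#' @param config A [calibration_config()].
#' @param geom,protocol Geometry/protocol for the homogeneous predictor.
#' @param form Energy form for the homogeneous predictor.
#' @return An object of class `calibration_result`: `params` (best-fit
#'   [hgo_params()]), `residual_norm` (the objective), `r_squared`,
#'   `fitted` (model force vector), `starts` (per-start diagnostics),
#'   `predictor`, `degenerate` (TRUE when every point is weighted zero),
#'   `wall_time` (s).
#' @export
calibrate <- function(exp_curve, thickness, predictor = "homogeneous",
                      config = calibration_config(),
                      geom = rake_geometry(), protocol = loading_protocol(),
                      form = "standard") {
  t0 <- Sys.time()
  exp_forces <- if (inherits(exp_curve, "force_curve"))
    force_vector(exp_curve) else as.numeric(exp_curve)
  if (any(!is.finite(exp_forces)))
    stop("experimental forces contain non-finite values")
  stopifnot(inherits(config, "calibration_config"))
  pr <- resolve_predictor(predictor, geom, protocol, form)
  lower <- config$lower; upper <- config$upper
  if (!is.null(pr$space)) {          # restrict to the surrogate's space
    lower <- pmax(lower, pr$space$lower[1:4])
    upper <- pmin(upper, pr$space$upper[1:4])
  }
  w <- force_weight(exp_forces)
  degenerate <- all(w == 0)
  if (degenerate)
    warning("all experimental forces fall below 30 mN: objective is identically zero and parameters are unidentifiable")

  resid_fn <- function(theta) {
    f <- tryCatch(pr$fn(theta, thickness), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f)))
      return(rep(1e8, length(exp_forces)))   # large penalty keeps solver alive
    w * (exp_forces - f)
  }
  jac_fn <- if (is.null(pr$jac)) NULL else function(theta) {
    J <- tryCatch(pr$jac(theta, thickness), error = function(e) NULL)
    if (is.null(J) || any(!is.finite(J)))
      return(matrix(0, length(exp_forces), 4L))
    -w * J
  }

  starts <- multistart_points(config)
  # clamp starts into the (possibly restricted) box
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))
  per_start <- vector("list", length(starts))
  best <- NULL
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = config$ftol, ptol = config$ptol,
                           maxiter = config$max_iter)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      per_start[[i]] <- list(start = starts[[i]], ok = FALSE,
                             message = conditionMessage(fit))
      next
    }
    obj <- sum(resid_fn(fit$par)^2)
    per_start[[i]] <- list(start = starts[[i]], par = fit$par,
                           objective = obj, ok = TRUE,
                           iterations = fit$niter, info = fit$info)
    if (is.null(best) || obj < best$objective - 0)
      best <- list(index = i, par = fit$par, objective = obj)
  }
  if (is.null(best))
    stop("all calibration starts failed: ",
         paste(vapply(per_start, function(s) s$message %||% "", ""), collapse = "; "))

  fitted <- pr$fn(as.numeric(best$par), thickness)
  r2 <- if (stats::sd(exp_forces) > 0) r_squared(exp_forces, fitted) else NA_real_
  structure(list(params = as_hgo_params(as.numeric(best$par)),
                 residual_norm = best$objective,
                 r_squared = r2, fitted = fitted,
                 exp_forces = exp_forces, thickness = thickness,
                 best_start = best$index, starts = per_start,
                 predictor = pr$label, degenerate = degenerate,
                 wall_time = as.numeric(Sys.time() - t0, units = "secs")),
            class = "calibration_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result (", x$predictor, " predictor):\n", sep = "")
  print(x$params)
  cat(sprintf("  residual norm = %.4g, R^2 = %.4f, best start = %d/%d, %.2f s\n",
              x$residual_norm, x$r_squared, x$best_start, length(x$starts),
              x$wall_time))
  invisible(x)
}

#' Coefficient of determination between measured and fitted forces
#'
#' `R^2 = 1 - sum((F_exp - F_num)^2) / sum((F_exp - mean(F_exp))^2)`.
#'
#' @param exp_forces Measured force vector (or [force_curve()]).
#' @param pred_forces Model force vector (or [force_curve()]).
#' @return Scalar `R^2` (at most 1; negative when the fit is worse than
#'   the mean).
#' @export
r_squared <- function(exp_forces, pred_forces) {
  if (inherits(exp_forces, "force_curve")) exp_forces <- force_vector(exp_forces)
  if (inherits(pred_forces, "force_curve")) pred_forces <- force_vector(pred_forces)
  stopifnot(length(exp_forces) == length(pred_forces))
  den <- sum((exp_forces - mean(exp_forces))^2)
  if (den == 0) stop("zero variance in the measured forces: R^2 undefined")
  1 - sum((exp_forces - pred_forces)^2) / den
}

#' Export a calibration result
#'
#' Writes the identified parameters and fit metrics as JSON and the
#' fitted-versus-measured curves as CSV next to it.
#'
#' @param result A `calibration_result`.
#' @param path Output JSON path; the CSV takes the same stem.
#' @return `path`, invisibly.
#' @export
export_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  obj <- list(params = unclass(result$params),
              residual_norm = result$residual_norm,
              r_squared = result$r_squared,
              thickness = result$thickness,
              predictor = result$predictor,
              best_start = result$best_start,
              degenerate = result$degenerate,
              wall_time = result$wall_time)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  p <- length(result$exp_forces) / 2
  utils::write.csv(data.frame(
    direction = rep(c("axial", "circumferential"), each = p),
    measured = result$exp_forces, fitted = result$fitted),
    sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
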
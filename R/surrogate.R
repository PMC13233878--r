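#' Material parameter space for surrogate training
#'
#' Box bounds over `(C10, k1, k2, kappa, t)` used to sample training
#' designs and to restrict surrogate-based calibration. Defaults are the
#' refined space: `C10` 0.01--2.0 kPa, `k1` 0.005--1.0 kPa, `k2`
#' 1.0--10.0, `kappa` 0.0--0.10, thickness 1.24--2.84 mm.
#'
#' @param lower,upper Named numeric vectors with entries
#'   `C10, k1, k2, kappa, t`.
#' @return An object of class `parameter_space`.
#' @export
parameter_space <- function(
    lower = c(C10 = 0.01, k1 = 0.005, k2 = 1.0, kappa = 0.0, t = 1.24),
    upper = c(C10 = 2.0, k1 = 1.0, k2 = 10.0, kappa = 0.10, t = 2.84)) {
  nm <- c("C10", "k1", "k2", "kappa", "t")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)))
  lower <- lower[nm]; upper <- upper[nm]
  if (any(lower >= upper)) stop("each lower bound must be below its upper bound")
  if (upper[["kappa"]] > 1 / 3) stop("kappa upper bound exceeds 1/3")
  structure(list(lower = lower, upper = upper, names = nm),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("Parameter space:\n")
  for (nm in x$names)
    cat(sprintf("  %-6s %g .. %g\n", nm, x$lower[[nm]], x$upper[[nm]]))
  invisible(x)
}

#' Latin hypercube sample of the parameter space
#'
#' Draws `n` designs such that each parameter's values occupy `n`
#' distinct equal-probability strata (the Latin property). The default
#' `"maximin"` variant additionally spreads the points by maximizing the
#' minimum inter-point distance, which stabilizes surrogate accuracy at
#' the corners of the space where the force response is most extreme;
#' `"random"` gives a plain random Latin hypercube. Deterministic for a
#' fixed seed.
#'
#' @param space A [parameter_space()].
#' @param n Number of designs.
#' @param seed Integer RNG seed.
#' @param method `"maximin"` (default) or `"random"`.
#' @return An `n x 5` matrix with columns `C10, k1, k2, kappa, t`.
#' @export
lhs_sample <- function(space, n, seed = 1L, method = c("maximin", "random")) {
  stopifnot(inherits(space, "parameter_space"), n >= 1)
  method <- match.arg(method)
  u <- withr_seed(seed, if (method == "maximin")
    lhs::maximinLHS(as.integer(n), 5L) else lhs::randomLHS(as.integer(n), 5L))
  X <- sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  colnames(X) <- space$names
  X
}

# evaluate an expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate the surrogate training set
#'
#' Evaluates a forward model on each sampled design. Designs whose
#' forward evaluation fails or returns non-finite forces are replaced by
#' fresh Latin hypercube draws (logged in the `resampled` attribute); if
#' more than 10% of designs fail the generation aborts.
#'
#' @param space A [parameter_space()].
#' @param n Number of designs.
#' @param forward Forward map `function(theta4, thickness) -> force vector`;
#'   defaults to the homogeneous analytic model under `geom`/`protocol`.
#' @param geom,protocol Geometry and protocol for the default forward map.
#' @param seed Integer seed (controls the design sample and any
#'   replacement draws).
#' @return List with `designs` (n x 5) and `forces` (n x 2p matrix).
#' @export
generate_training_set <- function(space, n, forward = NULL,
                                  geom = rake_geometry(),
                                  protocol = loading_protocol(), seed = 1L) {
  stopifnot(inherits(space, "parameter_space"))
  if (is.null(forward))
    forward <- function(theta, t) forward_map_homogeneous(theta, t, geom, protocol)
  X <- lhs_sample(space, n, seed)
  eval_row <- function(x) tryCatch({
    f <- forward(x[1:4], x[[5]])
    if (all(is.finite(f))) f else NULL
  }, error = function(e) NULL)
  rows <- lapply(seq_len(n), function(i) eval_row(X[i, ]))
  failed <- which(vapply(rows, is.null, logical(1)))
  n_resampled <- 0L
  if (length(failed) > n / 10)
    stop(sprintf("forward model failed on %d of %d designs (> 10%%)",
                 length(failed), n))
  attempt <- 1L
  while (length(failed) > 0 && attempt <= 20L) {
    Xr <- lhs_sample(space, max(length(failed), 2L), seed + 1000L * attempt)
    for (i in seq_along(failed)) {
      f <- eval_row(Xr[i, ])
      if (!is.null(f)) {
        X[failed[i], ] <- Xr[i, ]
        rows[[failed[i]]] <- f
        n_resampled <- n_resampled + 1L
      }
    }
    failed <- which(vapply(rows, is.null, logical(1)))
    attempt <- attempt + 1L
  }
  if (length(failed))
    stop("could not obtain forward evaluations for all designs")
  Y <- do.call(rbind, rows)
  structure(list(designs = X, forces = Y), resampled = n_resampled)
}

#' Surrogate training configuration
#'
#' The network is a fully connected feedforward net, 5 inputs
#' `(C10, k1, k2, kappa, t)`, two tanh-sigmoid hidden layers (128 and 64
#' units) and a linear output layer with one unit per sampled force
#' value. Training minimizes a regularized least-squares loss by
#' full-batch quasi-Newton (L-BFGS) iterations; one iteration is counted
#' as one epoch. Training stops when the loss MSE reaches `mse_target`,
#' when the loss-gradient max-norm falls below `grad_tol`, or at
#' `max_epochs`.
#'
#' @param hidden Hidden layer sizes.
#' @param max_epochs Epoch (iteration) budget.
#' @param mse_target MSE stopping target in the normalized output space.
#' @param grad_tol Gradient max-norm floor.
#' @param l2 L2 weight penalty (fixed weight decay; recorded in the
#'   model metadata as `regularization = "l2"`).
#' @param chunk Epochs per optimizer restart (history is recorded at
#'   chunk boundaries).
#' @param seed Seed for the weight initialization.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(hidden = c(128L, 64L), max_epochs = 1000L,
                             mse_target = 1e-7, grad_tol = 1e-4,
                             l2 = 1e-10, chunk = 200L, seed = 1L) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1), max_epochs >= 1,
            mse_target > 0, grad_tol >= 0, l2 >= 0, chunk >= 1)
  structure(list(hidden = as.integer(hidden), max_epochs = as.integer(max_epochs),
                 mse_target = mse_target, grad_tol = grad_tol, l2 = l2,
                 chunk = as.integer(chunk), seed = as.integer(seed)),
            class = "surrogate_config")
}

# ---- internal MLP machinery ----------------------------------------------

mlp_sizes <- function(n_in, hidden, n_out) c(n_in, hidden, n_out)

mlp_count <- function(sizes)
  sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])

mlp_unpack <- function(w, sizes) {
  L <- vector("list", length(sizes) - 1L)
  o <- 0L
  for (l in seq_along(L)) {
    ni <- sizes[l]; no <- sizes[l + 1]
    L[[l]] <- list(W = matrix(w[o + seq_len(ni * no)], ni, no),
                   b = w[o + ni * no + seq_len(no)])
    o <- o + ni * no + no
  }
  L
}

mlp_init <- function(sizes, seed) {
  withr_seed(seed, {
    w <- numeric(mlp_count(sizes))
    o <- 0L
    for (l in seq_len(length(sizes) - 1L)) {
      ni <- sizes[l]; no <- sizes[l + 1]
      w[o + seq_len(ni * no)] <- stats::rnorm(ni * no, 0, sqrt(2 / (ni + no)))
      o <- o + ni * no + no        # biases start at zero
    }
    w
  })
}

# forward pass: tanh hidden layers, linear output
mlp_forward <- function(w, sizes, A) {
  L <- mlp_unpack(w, sizes)
  H <- vector("list", length(L))
  X <- A
  for (l in seq_len(length(L) - 1L)) {
    X <- tanh(sweep(X %*% L[[l]]$W, 2, L[[l]]$b, "+"))
    H[[l]] <- X
  }
  last <- length(L)
  O <- sweep(X %*% L[[last]]$W, 2, L[[last]]$b, "+")
  list(H = H, O = O, L = L)
}

# loss = sum((Wt * (O - S))^2) / (n*m)  + l2 * sum(w^2), with gradient.
# `mse` is the plain mean squared error in the standardized output space
# (the quantity the stopping target refers to); the weighted term drives
# the optimizer.
mlp_loss_grad <- function(w, sizes, A, S, Wt, l2) {
  f <- mlp_forward(w, sizes, A)
  nm <- length(S)
  R <- Wt * (f$O - S)
  loss <- sum(R^2) / nm + l2 * sum(w^2)
  mse_std <- mean((f$O - S)^2)
  D <- 2 * Wt * R / nm
  nl <- length(f$L)
  grads <- vector("list", nl)
  for (l in nl:1) {
    X <- if (l == 1) A else f$H[[l - 1]]
    grads[[l]] <- list(W = crossprod(X, D), b = colSums(D))
    if (l > 1) D <- (D %*% t(f$L[[l]]$W)) * (1 - f$H[[l - 1]]^2)
  }
  g <- unlist(lapply(grads, function(gl) c(gl$W, gl$b))) + 2 * l2 * w
  list(loss = loss, grad = g, mse = mse_std)
}

#' Train the feedforward surrogate
#'
#' Fits the network mapping `(C10, k1, k2, kappa, t)` to the sampled
#' force vector. Inputs are min--max scaled to `[-1, 1]` over the space
#' bounds. Outputs are passed through `asinh` (logarithmic for large
#' forces, linear near zero) and standardized per output index; the
#' least-squares residuals are then weighted back to force scale
#' (delta-method weights `cosh(z) * sd_j`, normalized by the total force
#' norm) so the training loss matches the pooled relative error that
#' validation measures. Weight decay provides the regularization.
#'
#' @param designs `n x 5` design matrix from [generate_training_set()].
#' @param forces `n x m` force matrix (mN).
#' @param config A [surrogate_config()].
#' @param space The [parameter_space()] the designs were drawn from
#'   (stored for input scaling and extrapolation checks).
#' @return An object of class `surrogate_model` with weights, scalers,
#'   architecture, training history (MSE per recorded epoch) and stop
#'   reason (`mse_target`, `gradient_floor` or `max_epochs`).
#' @export
train_surrogate <- function(designs, forces, config = surrogate_config(),
                            space = parameter_space()) {
  stopifnot(is.matrix(designs), is.matrix(forces),
            nrow(designs) == nrow(forces), ncol(designs) == 5L)
  if (nrow(designs) < 50)
    stop("at least 50 training designs are required")
  if (any(!is.finite(forces))) stop("non-finite forces in training set")
  lower <- space$lower; upper <- space$upper
  A <- scale_inputs(designs, space)
  Z <- asinh(forces)
  mu <- colMeans(Z)
  sg <- apply(Z, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  S <- sweep(sweep(Z, 2, mu, "-"), 2, sg, "/")
  Wt <- sweep(cosh(Z), 2, sg, "*") / sqrt(sum(forces^2))
  sizes <- mlp_sizes(5L, config$hidden, ncol(forces))
  w <- mlp_init(sizes, config$seed)

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mse = numeric(0), grad_norm = numeric(0))
  epochs_done <- 0L
  stop_reason <- "max_epochs"
  fn <- function(w) mlp_loss_grad(w, sizes, A, S, Wt, config$l2)$loss
  gr <- function(w) mlp_loss_grad(w, sizes, A, S, Wt, config$l2)$grad
  while (epochs_done < config$max_epochs) {
    iters <- min(config$chunk, config$max_epochs - epochs_done)
    res <- stats::optim(w, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = iters, factr = 10))
    w <- res$par
    epochs_done <- epochs_done + iters
    lg <- mlp_loss_grad(w, sizes, A, S, Wt, config$l2)
    if (any(!is.finite(w)) || !is.finite(lg$loss))
      stop("training diverged (NaN loss); inspect the force scaling")
    # gradient floor on the summed-squared-residual scale (the mean-loss
    # gradient is nm times smaller and would trip the floor prematurely)
    gn <- max(abs(lg$grad)) * length(S)
    history <- rbind(history, data.frame(epoch = epochs_done, loss = lg$loss,
                                         mse = lg$mse, grad_norm = gn))
    if (lg$mse <= config$mse_target) { stop_reason <- "mse_target"; break }
    if (gn <= config$grad_tol) { stop_reason <- "gradient_floor"; break }
  }

  structure(list(weights = w, sizes = sizes,
                 input_lower = lower, input_upper = upper,
                 output_mu = mu, output_sd = sg,
                 space = space, config = config,
                 regularization = "l2",
                 history = history, stop_reason = stop_reason,
                 epochs = epochs_done, n_train = nrow(designs)),
            class = "surrogate_model")
}

# strictly positive parameters enter the network through log: the
# (asinh-)force surface behaves like log(k1) + log(t) + smooth terms, so
# log coordinates linearize the dominant dependence and remove the
# near-singular gradient at the lower k1 / C10 edges. kappa may be zero
# and k2's influence is already nearly linear, so both stay untransformed.
.input_log <- c(C10 = TRUE, k1 = TRUE, k2 = FALSE, kappa = FALSE, t = TRUE)

warp_inputs <- function(X) {
  X <- as.matrix(X)
  for (j in which(.input_log)) X[, j] <- log(X[, j])
  X
}

scale_inputs <- function(X, space) {
  lo <- space$lower; hi <- space$upper
  lo[.input_log] <- log(lo[.input_log])
  hi[.input_log] <- log(hi[.input_log])
  ctr <- (lo + hi) / 2
  hw <- (hi - lo) / 2
  sweep(sweep(warp_inputs(X), 2, ctr, "-"), 2, hw, "/")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "Surrogate model: %s network, %d weights, trained %d epochs (%s), n = %d designs\n",
    paste(x$sizes, collapse = "-"), length(x$weights), x$epochs,
    x$stop_reason, x$n_train))
  invisible(x)
}

#' Predict a force curve with the surrogate
#'
#' Evaluates the trained network at given HGO parameters and thickness.
#' Inputs more than 10% of the parameter range outside the training
#' space trigger a warning (the network extrapolates there).
#'
#' @param model A `surrogate_model`.
#' @param params [hgo_params()] or length-4 vector.
#' @param thickness Sample thickness, mm.
#' @return Numeric force vector (mN), axial block first.
#' @export
predict_forces <- function(model, params, thickness) {
  stopifnot(inherits(model, "surrogate_model"))
  p <- as_hgo_params(params)
  x <- c(p$C10, p$k1, p$k2, p$kappa, thickness)
  rng <- model$input_upper - model$input_lower
  over <- pmax(model$input_lower - x, x - model$input_upper, 0) / rng
  if (any(over > 0.1))
    warning(sprintf("surrogate evaluated %0.f%% of range outside its training space (%s)",
                    100 * max(over), model$space$names[which.max(over)]))
  A <- scale_inputs(matrix(x, 1), model$space)
  O <- mlp_forward(model$weights, model$sizes, A)$O
  as.vector(sinh(sweep(sweep(O, 2, model$output_sd, "*"), 2, model$output_mu, "+")))
}

# analytic Jacobian of the surrogate force prediction wrt the four
# material parameters (thickness held fixed), by backpropagation through
# the network and the output transform. Used by the calibration solver.
surrogate_force_jac <- function(model, params, thickness) {
  p <- as_hgo_params(params)
  x <- c(p$C10, p$k1, p$k2, p$kappa, thickness)
  A <- scale_inputs(matrix(x, 1), model$space)
  f <- mlp_forward(model$weights, model$sizes, A)
  nl <- length(f$L)
  # J = dO/dA : start from identity on the output and run the chain backwards
  J <- t(f$L[[nl]]$W)                      # n_out x n_{last hidden}
  for (l in (nl - 1):1) {
    J <- (J * rep((1 - f$H[[l]]^2), each = nrow(J))) %*% t(f$L[[l]]$W)
  }
  z <- sweep(sweep(f$O, 2, model$output_sd, "*"), 2, model$output_mu, "+")
  lo <- model$input_lower; hi <- model$input_upper
  lo[.input_log] <- log(lo[.input_log])
  hi[.input_log] <- log(hi[.input_log])
  hw <- (hi - lo) / 2
  # dF/dtheta_j = cosh(z) sd J[, j] / hw_j * dwarp_j/dtheta_j
  dF <- J[, 1:4, drop = FALSE] *
    as.vector(cosh(z) * model$output_sd)
  dF <- sweep(dF, 2, hw[1:4], "/")
  dwarp <- ifelse(.input_log[1:4], 1 / x[1:4], 1)
  sweep(dF, 2, dwarp, "*")
}

#' Validate a surrogate with the pooled NRMSE
#'
#' Normalized root mean square error in percent,
#' `sqrt(sum((F_pred - F_ref)^2) / sum(F_ref^2)) * 100`, pooled over all
#' `m = n_test x outputs` force values, plus the per-sample NRMSE
#' distribution.
#'
#' @param model A `surrogate_model`.
#' @param test_designs `n_test x 5` design matrix (disjoint from training).
#' @param test_forces `n_test x m` reference forces from the forward model.
#' @return A list of class `validation_report`: `nrmse` (%), `m`,
#'   `per_sample` (vector of per-design NRMSE %).
#' @export
validate_nrmse <- function(model, test_designs, test_forces) {
  stopifnot(inherits(model, "surrogate_model"), is.matrix(test_designs),
            is.matrix(test_forces), nrow(test_designs) == nrow(test_forces))
  if (all(test_forces == 0)) stop("all-zero reference forces: NRMSE undefined")
  pred <- t(apply(test_designs, 1, function(x)
    suppressWarnings(predict_forces(model, x[1:4], x[[5]]))))
  num <- rowSums((pred - test_forces)^2)
  den <- rowSums(test_forces^2)
  structure(list(nrmse = sqrt(sum(num) / sum(den)) * 100,
                 m = length(test_forces),
                 per_sample = sqrt(num / pmax(den, .Machine$double.xmin)) * 100),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Surrogate validation: pooled NRMSE %.3f%% over m = %d force values\n",
              x$nrmse, x$m))
  invisible(x)
}

#' Save / load a surrogate model as portable JSON
#'
#' The file stores the architecture, weights, scalers, space bounds and
#' training provenance (config, history, stop reason) as plain JSON.
#'
#' @param model A `surrogate_model`.
#' @param path File path (`.json`).
#' @return `path` invisibly; `load_surrogate()` returns the model.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  obj <- list(weights = model$weights, sizes = model$sizes,
              input_lower = as.list(model$input_lower),
              input_upper = as.list(model$input_upper),
              output_mu = model$output_mu, output_sd = model$output_sd,
              config = unclass(model$config),
              regularization = model$regularization,
              history = model$history, stop_reason = model$stop_reason,
              epochs = model$epochs, n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- parameter_space(lower = unlist(obj$input_lower),
                           upper = unlist(obj$input_upper))
  structure(list(weights = obj$weights, sizes = obj$sizes,
                 input_lower = space$lower, input_upper = space$upper,
                 output_mu = obj$output_mu, output_sd = obj$output_sd,
                 space = space,
                 config = do.call(surrogate_config, obj$config[
                   c("hidden", "max_epochs", "mse_target", "grad_tol",
                     "l2", "chunk", "seed")]),
                 regularization = obj$regularization,
                 history = obj$history, stop_reason = obj$stop_reason,
                 epochs = obj$epochs, n_train = obj$n_train),
            class = "surrogate_model")
}
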
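test_that("force weighting follows the reliability tiers", {
  expect_identical(force_weight(150), 2L)
  expect_identical(force_weight(100), 2L)   # boundary inclusive
  expect_identical(force_weight(50), 1L)
  expect_identical(force_weight(30), 1L)    # boundary inclusive
  expect_identical(force_weight(10), 0L)
  expect_identical(force_weight(c(150, 50, 10)), c(2L, 1L, 0L))
})

test_that("objective reproduces the hand-computed weighted sum", {
  exp_f <- c(150, 50, 10)
  num_f <- c(140, 60, 0)
  pred <- function(theta, t) num_f
  phi <- calibration_objective(c(1, 0, 0, 0) + c(0, 0, 0, 0.0),
                               exp_f, predictor = pred, thickness = 2)
  expect_equal(phi, (2 * 10)^2 + (1 * (-10))^2 + 0)   # = 500
  # exact prediction -> 0
  expect_equal(calibration_objective(c(1, 0, 0, 0), exp_f,
                                     predictor = function(a, b) exp_f,
                                     thickness = 2), 0)
  # fully masked curve -> 0 regardless of the prediction
  expect_equal(calibration_objective(c(1, 0, 0, 0), c(5, 10, 29),
                                     predictor = function(a, b) c(0, 0, 0),
                                     thickness = 2), 0)
})

test_that("multistart points start from the fixed guess and stay in bounds", {
  cfg <- calibration_config()
  p1 <- multistart_points(calibration_config(n_starts = 1))
  expect_length(p1, 1)
  expect_equal(p1[[1]], cfg$initial)
  pts <- multistart_points(cfg)
  expect_length(pts, 3)
  expect_equal(pts[[1]], cfg$initial)
  for (p in pts)
    expect_true(all(p >= cfg$lower & p <= cfg$upper))
  expect_equal(multistart_points(cfg), pts)   # seeded, reproducible
})

test_that("R-squared matches its definition", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("noiseless curves are inverted back to their generating parameters", {
  truth <- c(C10 = 0.45, k1 = 0.3, k2 = 4.5, kappa = 0.06)
  g <- std_geom(1.7)
  fc <- homogeneous_forward(as_hgo_params(truth), g)
  res <- calibrate(fc, thickness = 1.7, predictor = "homogeneous", geom = g)
  est <- unlist(unclass(res$params))
  expect_lt(abs(est[["C10"]] - truth[["C10"]]) / truth[["C10"]], 0.02)
  expect_lt(abs(est[["k1"]] - truth[["k1"]]) / truth[["k1"]], 0.02)
  expect_lt(abs(est[["k2"]] - truth[["k2"]]) / truth[["k2"]], 0.02)
  expect_lt(abs(est[["kappa"]] - truth[["kappa"]]), 0.005)
  expect_gt(res$r_squared, 0.999)
})

test_that("the multistart best never exceeds a single-start objective", {
  g <- std_geom(2)
  fc <- force_vector(homogeneous_forward(trachea_mean(), g))
  noisy <- withr::with_seed(5, fc + stats::rnorm(50, 0, 5 + 0.01 * abs(fc)))
  single <- calibrate(noisy, 2, config = calibration_config(n_starts = 1),
                      geom = g)
  multi <- calibrate(noisy, 2, config = calibration_config(n_starts = 3),
                     geom = g)
  expect_lte(multi$residual_norm, single$residual_norm + 1e-9)
})

test_that("all-noise curves are flagged as degenerate with a flat objective", {
  sub30 <- rep(15, 50)
  expect_warning(res <- calibrate(sub30, 2, predictor = function(a, b) rep(0, 50)),
                 "below 30 mN")
  expect_true(res$degenerate)
  expect_equal(res$residual_norm, 0)
  # the objective is flat in the parameters
  o1 <- calibration_objective(c(0.1, 0.1, 1, 0), sub30,
                              predictor = function(a, b) rep(0, 50), thickness = 2)
  o2 <- calibration_objective(c(5, 5, 9, 0.3), sub30,
                              predictor = function(a, b) rep(1e3, 50), thickness = 2)
  expect_equal(o1, 0)
  expect_equal(o2, 0)
})

test_that("predictor failures are absorbed as penalties, not crashes", {
  bad <- function(theta, t) stop("solver blew up")
  expect_equal(calibration_objective(c(1, 0.1, 1, 0), c(150, 40, 10),
                                     predictor = bad, thickness = 2), 1e30)
  # a predictor that fails in part of the space keeps the optimizer alive:
  # calibration completes and returns finite diagnostics for every start
  g <- std_geom(2)
  fc <- force_vector(homogeneous_forward(trachea_mean(), g))
  flaky <- function(theta, t) {
    if (theta[1] > 5) stop("diverged")
    forward_map_homogeneous(theta, t, g)
  }
  res <- calibrate(fc, 2, predictor = flaky)
  expect_true(all(vapply(res$starts, function(s) isTRUE(s$ok), logical(1))))
  expect_true(is.finite(res$residual_norm))
})

test_that("surrogate-based calibration is confined to the training space", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 80, seed = 21)
  m <- train_surrogate(ts$designs, ts$forces,
                       surrogate_config(hidden = c(16, 8), max_epochs = 300,
                                        chunk = 150, seed = 4))
  fc <- force_vector(homogeneous_forward(trachea_mean(), std_geom(2)))
  res <- calibrate(fc, 2, predictor = m,
                   config = calibration_config(n_starts = 2))
  expect_identical(res$predictor, "surrogate")
  est <- unlist(unclass(res$params))
  expect_true(all(est >= sp$lower[1:4] - 1e-9))
  expect_true(all(est <= sp$upper[1:4] + 1e-9))
})

test_that("calibration results export to JSON and CSV", {
  g <- std_geom(2)
  fc <- homogeneous_forward(trachea_mean(), g)
  res <- calibrate(fc, 2, geom = g)
  path <- tempfile(fileext = ".json")
  export_calibration(res, path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(out$params$C10, res$params$C10, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.json$", ".csv", path)))
})
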
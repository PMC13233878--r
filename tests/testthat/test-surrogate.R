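test_that("Latin hypercube samples respect bounds and the Latin property", {
  sp <- parameter_space()
  X1 <- lhs_sample(sp, 1, seed = 3)
  expect_true(all(X1 >= sp$lower & X1 <= sp$upper))
  X <- lhs_sample(sp, 10, seed = 3)
  for (j in 1:5) {
    u <- (X[, j] - sp$lower[j]) / (sp$upper[j] - sp$lower[j])
    expect_equal(sort(floor(u * 10)), 0:9)   # one sample per decile
  }
  expect_identical(lhs_sample(sp, 10, seed = 3), X)
  expect_false(identical(lhs_sample(sp, 10, seed = 4), X))
})

test_that("training-set generation is reproducible and finite", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 5, seed = 9)
  expect_equal(dim(ts$forces), c(5, 50))
  expect_true(all(is.finite(ts$forces)))
  # any row regenerated from its design reproduces the stored row exactly
  i <- 3
  expect_identical(ts$forces[i, ],
                   forward_map_homogeneous(ts$designs[i, 1:4],
                                           ts$designs[i, 5]))
  # failing forward models are replaced by fresh draws; > 10% failure aborts
  flaky <- function(theta, t) if (theta[3] > 5.5) stop("diverged") else
    forward_map_homogeneous(theta, t)
  expect_error(generate_training_set(sp, 20, forward = flaky, seed = 1),
               "10%")
})

test_that("force magnitudes across the space span the weighting tiers", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 60, seed = 2)
  peaks <- apply(ts$forces, 1, max)
  expect_true(any(peaks < 30))     # noise-dominated samples exist
  expect_true(any(peaks > 100))    # reliable-range samples exist
})

test_that("a small surrogate trains deterministically and records stopping", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 80, seed = 5)
  cfg <- surrogate_config(hidden = c(16, 8), max_epochs = 150, chunk = 50,
                          seed = 11)
  m1 <- train_surrogate(ts$designs, ts$forces, cfg)
  m2 <- train_surrogate(ts$designs, ts$forces, cfg)
  expect_identical(m1$weights, m2$weights)   # bit-reproducible under the seed
  expect_true(m1$stop_reason %in% c("mse_target", "gradient_floor", "max_epochs"))
  expect_true(nrow(m1$history) >= 1)
  expect_true(all(diff(m1$history$loss) <= 1e-12))  # optimizer loss non-increasing
  # unreachably small tolerances force the epoch cap
  cfg2 <- surrogate_config(hidden = c(8), max_epochs = 30, chunk = 30,
                           mse_target = 1e-30, grad_tol = 0, seed = 11)
  m3 <- train_surrogate(ts$designs, ts$forces, cfg2)
  expect_identical(m3$stop_reason, "max_epochs")
  expect_identical(m3$epochs, 30L)
})

test_that("training rejects undersized or non-finite inputs", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 49, seed = 5)
  expect_error(train_surrogate(ts$designs, ts$forces), "50 training designs")
  ts2 <- generate_training_set(sp, 50, seed = 5)
  bad <- ts2$forces; bad[1, 1] <- NaN
  expect_error(train_surrogate(ts2$designs, bad), "non-finite")
})

test_that("in-sample predictions are close and out-of-space inputs warn", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 150, seed = 6)
  m <- train_surrogate(ts$designs, ts$forces,
                       surrogate_config(hidden = c(32, 16), max_epochs = 800,
                                        chunk = 400, seed = 2))
  # the pooled in-sample error is what the weighted loss controls; the
  # relative error on individual low-force designs is deliberately loose
  r <- validate_nrmse(m, ts$designs, ts$forces)
  expect_lt(r$nrmse, 10)
  expect_warning(predict_forces(m, c(5, 0.5, 5, 0.05), 2), "outside")
  expect_true(all(is.finite(predict_forces(m, c(2, 1, 10, 0.1), 2.84))))
})

test_that("NRMSE has the defining algebraic properties", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 60, seed = 8)
  m <- train_surrogate(ts$designs, ts$forces,
                       surrogate_config(hidden = c(8), max_epochs = 40,
                                        chunk = 40, seed = 3))
  # identical predictions -> 0%; doubled references -> 100%
  pred <- t(apply(ts$designs, 1, function(x)
    predict_forces(m, x[1:4], x[[5]])))
  expect_equal(nrmse_direct(pred, pred), 0)
  expect_equal(nrmse_direct(2 * ts$forces, ts$forces), 100)
  rep <- validate_nrmse(m, ts$designs, ts$forces)
  expect_equal(rep$m, 60 * 50)
  expect_equal(rep$nrmse, nrmse_direct(pred, ts$forces), tolerance = 1e-10)
  expect_error(validate_nrmse(m, ts$designs, ts$forces * 0), "all-zero")
})

test_that("surrogates survive a JSON save/load round trip", {
  sp <- parameter_space()
  ts <- generate_training_set(sp, 60, seed = 8)
  m <- train_surrogate(ts$designs, ts$forces,
                       surrogate_config(hidden = c(8), max_epochs = 30,
                                        chunk = 30, seed = 3))
  path <- tempfile(fileext = ".json")
  save_surrogate(m, path)
  m2 <- load_surrogate(path)
  x <- ts$designs[5, ]
  expect_equal(predict_forces(m2, x[1:4], x[[5]]),
               predict_forces(m, x[1:4], x[[5]]), tolerance = 1e-12)
  expect_identical(m2$stop_reason, m$stop_reason)
  expect_identical(m2$regularization, "l2")
})

test_that("surrogate accuracy improves with training-set size", {
  sp <- parameter_space()
  te <- generate_training_set(sp, 40, seed = 99)
  nrmse_at <- function(n) {
    ts <- generate_training_set(sp, n, seed = 13)
    m <- train_surrogate(ts$designs, ts$forces,
                         surrogate_config(hidden = c(24, 12), max_epochs = 800,
                                          chunk = 400, seed = 7))
    validate_nrmse(m, te$designs, te$forces)$nrmse
  }
  # endpoints of the size sweep: much more data must not hurt
  expect_lt(nrmse_at(400), nrmse_at(100))
})
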
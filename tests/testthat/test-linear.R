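test_that("the zero model is the lagged identity", {
  ps <- predict_zero(recording(matrix(c(3, 5, 4), 1)))
  expect_equal(as.numeric(ps$predictions), c(3, 5))
  expect_equal(as.numeric(ps$residuals), c(2, -1))
  expect_equal(ps$indices, 2:3)
  # residual alignment invariant
  expect_equal(ps$residuals, ps$actual - ps$predictions)
  # random walk: residuals recover the innovations exactly
  set.seed(1)
  e <- rnorm(500)
  y <- cumsum(e)
  ps2 <- predict_zero(recording(matrix(y, 1)))
  expect_equal(as.numeric(ps2$residuals), e[-1])
})

test_that("dense least squares recovers the generating connectivity", {
  sim <- gen_stable_var(5, d = 1, T = 1e4, seed = 3)
  m <- fit_ar(sim$recording, d = 1, structure = "dense")
  expect_lt(max(abs(m$W - sim$truth$W)), 0.05)
})

test_that("structural constraints and the LASSO limit behave as required", {
  sim <- gen_stable_var(4, d = 2, T = 3000, seed = 5)
  sc <- fit_ar(sim$recording, d = 2, structure = "scalar")
  expect_true(all(sc$W[row(sc$W) != col(sc$W)] == 0))
  expect_true(all(sc$lags[[1]][row(sc$W) != col(sc$W)] == 0))

  big <- fit_ar(sim$recording, d = 1, structure = "sparse", lambda = 1e6)
  expect_true(all(big$W == 0))
  te <- recording(sim$recording$values[, 1:500])
  pl <- predict_linear(big, te)   # d = 1: same alignment as the zero model
  pz <- predict_zero(te)
  expect_equal(pl$predictions, pz$predictions, tolerance = 1e-12)
  expect_error(fit_ar(sim$recording, d = 1, lambda = -1),
               class = "pembench_invalid_parameter")
  expect_error(fit_ar(matrix(rnorm(8), 2), d = 5),
               class = "pembench_insufficient_samples")
})

test_that("least squares dominates the zero model on its own training data", {
  sim <- gen_stable_var(3, d = 1, T = 2000, seed = 9)
  m <- fit_ar(sim$recording, d = 1, structure = "dense")
  r_fit <- r2_score(predict_linear(m, sim$recording))$r2
  r_zero <- r2_score(predict_zero(sim$recording))$r2
  expect_true(all(r_fit >= r_zero - 1e-10))
})

test_that("training error is non-increasing in model order", {
  sim <- gen_stable_var(3, d = 3, T = 4000, seed = 21)
  sse <- vapply(1:3, function(d) {
    m <- fit_ar(sim$recording, d = d, structure = "dense", lag_mode = "full")
    ps <- predict_linear(m, sim$recording)
    cols <- ps$indices > 3  # score the same time points for every order
    sum(ps$residuals[, cols]^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-6))
})

test_that("predictions are causal: the current sample never leaks in", {
  sim <- gen_stable_var(3, d = 2, T = 1500, seed = 33)
  m <- fit_ar(sim$recording, d = 2, structure = "dense")
  te <- recording(sim$recording$values[, 1:300])
  ps <- predict_linear(m, te)
  pert <- te$values
  t_check <- 150L
  pert[, t_check] <- pert[, t_check] + 100
  ps2 <- predict_linear(m, recording(pert))
  col <- which(ps$indices == t_check)
  expect_equal(ps$predictions[, col], ps2$predictions[, col])
  # and the prediction at t_check + 1 must change
  expect_gt(max(abs(ps$predictions[, col + 1] - ps2$predictions[, col + 1])), 1)
})

test_that("a one-channel model reproduces the hand-computed arithmetic", {
  # y(t) = y(t-1) + W y(t-1): W = -0.5, y(t-1) = 2 -> prediction 1
  m <- structure(list(W = matrix(-0.5, 1, 1), lags = list(), d = 1L,
                      structure = "dense", lag_mode = "diagonal",
                      lambda = 0, center = 0, n = 1L, labels = "ch1",
                      fit_time = 0),
                 class = "linear_ar_model")
  ps <- predict_linear(m, recording(matrix(c(2, 7), 1)))
  expect_equal(as.numeric(ps$predictions), 1)
})
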
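test_that("an enormous bandwidth reduces the manifold model to global linear", {
  sim <- gen_stable_var(3, d = 1, T = 1200, seed = 2)
  ytr <- sim$recording$values[, 1:900]
  yte <- sim$recording$values[, 901:1200]
  mf <- manifold_predict(recording(ytr), recording(yte),
                         manifold_config(h = 1e6))
  # global linear reference: one unweighted least-squares plane (intercept +
  # lag-1 regressors) fit to the training first differences
  cf <- qr.coef(qr(cbind(1, t(ytr[, -900]))),
                t(ytr[, -1] - ytr[, -900]))
  glob <- yte[, -300] + t(cbind(1, t(yte[, -300])) %*% cf)
  rel <- max(abs(mf$predictions - glob)) / max(abs(glob))
  expect_lt(rel, 1e-6)
})

test_that("a local bandwidth captures a scalar sigmoidal map that linear cannot", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    N <- 1500
    y <- numeric(N); y[1] <- 0.1
    for (t in 2:N) y[t] <- tanh(y[t - 1] * 3) + rnorm(1, sd = 0.3)
    tr <- recording(matrix(y[1:1000], 1))
    te <- recording(matrix(y[1001:N], 1))
    r_m <- r2_score(manifold_predict(tr, te, manifold_config(h = 0.5)))$r2
    r_l <- r2_score(predict_linear(fit_ar(tr, d = 1, structure = "dense"), te))$r2
    r_m - r_l
  }, numeric(1))
  expect_gt(mean(wins), 0)
  expect_true(mean(wins > 0) >= 0.8)
})

test_that("local weights are 1 at zero distance and degrade to a global fit", {
  # weight at distance zero is exactly exp(0) = 1 by construction
  expect_equal(exp(-0 / (2 * 0.5^2)), 1)
  # queries astronomically far from training data fall back to global linear
  Xtr <- matrix(rnorm(60), 30, 2)
  ytr <- Xtr %*% c(1, -2) + rnorm(30, sd = 0.01)
  far <- matrix(c(1e8, 1e8), 1, 2)
  expect_warning(p <- local_linear_regression(Xtr, as.numeric(ytr), far,
                                              h = 0.1),
                 "global linear")
  cf <- qr.coef(qr(cbind(1, Xtr)), ytr)
  expect_equal(as.numeric(p), as.numeric(c(1, far) %*% cf), tolerance = 1e-8)
})

test_that("the MMSE predictor matches the linear one on jointly Gaussian data", {
  sim <- gen_stable_var(2, d = 1, T = 1e4, seed = 6)
  v <- sim$recording$values / apply(sim$recording$values[, 1:5000], 1, sd)
  tr <- recording(v[, 1:5000])
  te <- recording(v[, 5001:10000])
  mm <- suppressWarnings(
    mmse_predict(tr, te, mmse_config(beta = 0.02, n_bins = 100,
                                     mode = "pairwise")))
  # same conditioning set for the linear reference: scalar AR-1 per channel
  lin <- predict_linear(fit_ar(tr, d = 1, structure = "scalar"), te)
  gap <- r2_score(mm)$r2 - r2_score(lin)$r2
  expect_lt(max(abs(gap)), 0.02)
})

test_that("point-mass neighborhoods and flat windows hit their limits", {
  # each conditioning neighborhood holds one difference value: the weighted
  # histogram is a point mass and the prediction is that value (to within
  # half a bin width)
  x_tr <- c(rep(0, 5), rep(10, 5))
  y_tr <- c(rep(2, 5), rep(5, 5))
  p <- mmse_regression(x_tr, y_tr, c(0, 10), beta = 0.001, n_bins = 50)
  halfbin <- (5 - 2) / 50 / 2
  expect_lt(abs(p[1] - 2), halfbin + 1e-12)
  expect_lt(abs(p[2] - 5), halfbin + 1e-12)

  # a huge window makes every weight equal: the unconditional mean
  set.seed(4)
  x <- rnorm(400); y <- tanh(x)
  p2 <- mmse_regression(x, y, c(-2, 0, 2), beta = 1e6, n_bins = 100)
  expect_lt(max(abs(p2 - mean(y))), diff(range(y)) / 100 + 1e-6)

  expect_error(mmse_regression(rep(1, 10), rnorm(10), 1),
               class = "pembench_degenerate_signal")
})

test_that("scalar-mode MMSE conditions on own lags and stays aligned", {
  sim <- gen_stable_var(2, d = 2, T = 2500, seed = 12)
  tr <- recording(sim$recording$values[, 1:2000])
  te <- recording(sim$recording$values[, 2001:2500])
  mm <- suppressWarnings(
    mmse_predict(tr, te, mmse_config(beta = 0.05, mode = "scalar", d = 2)))
  expect_equal(mm$indices, 3:500)
  expect_equal(mm$residuals, mm$actual - mm$predictions)
  expect_identical(mm$fit_time, 0)
})
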
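test_that("prediction R-squared follows its definition including edge cases", {
  y <- matrix(rnorm(40), 2)
  expect_equal(r2_per_channel(y, y)$r2, c(1, 1), ignore_attr = TRUE)
  const <- matrix(rowMeans(y), 2, 20)
  expect_equal(r2_per_channel(y, const)$r2, c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(r2_per_channel(c(1, 2, 3), c(3, 3, 3))$r2, -1.5,
               ignore_attr = TRUE)
  mix <- rbind(rnorm(10), rep(2, 10))
  r <- r2_per_channel(mix, mix + 0.1)
  expect_true(is.na(r$r2[2]))  # constant test channel: undefined sentinel
  expect_false(is.na(r$r2[1]))
})

test_that("the portmanteau statistic matches a brute-force double sum", {
  set.seed(7)
  E <- matrix(rnorm(12), 2, 6)
  expect_equal(portmanteau_q(E, 2), oracle_portmanteau_q(E, 2),
               tolerance = 1e-10)
  E2 <- matrix(rnorm(60), 3, 20)
  expect_equal(portmanteau_q(E2, 5), oracle_portmanteau_q(E2, 5),
               tolerance = 1e-10)
  expect_equal(portmanteau_q(matrix(0, 2, 50), 5), 0)
  expect_error(portmanteau_q(E, 6), class = "pembench_invalid_parameter")
})

test_that("Q is invariant to channel permutation and invertible recombination", {
  set.seed(3)
  E <- matrix(rnorm(4 * 300), 4)
  q0 <- portmanteau_q(E, 10)
  expect_equal(portmanteau_q(E[c(3, 1, 4, 2), ], 10), q0, tolerance = 1e-8)
  Tm <- matrix(rnorm(16), 4); while (abs(det(Tm)) < 0.1) Tm <- matrix(rnorm(16), 4)
  expect_equal(portmanteau_q(Tm %*% E, 10), q0, tolerance = 1e-6)
})

test_that("strongly autocorrelated residuals are reliably rejected", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    E <- matrix(0, 2, 1000)
    for (t in 2:1000) E[, t] <- 0.9 * E[, t - 1] + rnorm(2)
    whiteness_test(E, M = 20, seed = s)$ratio > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the randomized threshold is reproducible and uses all shuffles", {
  set.seed(2)
  E <- matrix(rnorm(2 * 300), 2)
  w1 <- whiteness_test(E, M = 10, seed = 42)
  w2 <- whiteness_test(E, M = 10, seed = 42)
  expect_identical(w1$Q_thr, w2$Q_thr)
  expect_identical(w1$n_shuffles, 100L)
  expect_warning(whiteness_test(E, M = 10, n_shuffles = 10, seed = 1),
                 "unstable")
})

test_that("the univariate chi-squared whiteness test matches its brute force", {
  set.seed(5)
  e <- rnorm(300)
  res <- chi2_whiteness_univariate(e, 10)
  rho <- acf(e, lag.max = 10, plot = FALSE)$acf[-1]
  expect_equal(res$statistic, 300 * sum(rho^2), tolerance = 1e-10)
  # agreement with the standard implementation
  bt <- Box.test(e, lag = 10, type = "Box-Pierce")
  expect_equal(res$statistic, unname(bt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, bt$p.value, tolerance = 1e-10)
  lb <- chi2_whiteness_univariate(e, 10, type = "ljung-box")
  btl <- Box.test(e, lag = 10, type = "Ljung-Box")
  expect_equal(lb$statistic, unname(btl$statistic), tolerance = 1e-10)
  expect_identical(chi2_whiteness_univariate(e, 0),
                   list(statistic = 0, p_value = 1, M = 0L,
                        type = "box-pierce"))
  expect_error(chi2_whiteness_univariate(rep(1, 50), 5),
               class = "pembench_degenerate_signal")
})

test_that("white-noise p-values are uniform", {
  ps <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    chi2_whiteness_univariate(rnorm(1000), 20)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, punif))$p.value, 0.01)
})

test_that("cross-validation plans reproduce the protocol arithmetic", {
  scans <- lapply(1:4, function(i)
    recording(matrix(rnorm(5 * 1200), 5), sampling_interval = 0.72))
  plan <- build_cv_plan(scans, "fmri")
  expect_length(plan$folds, 8L)
  expect_true(all(vapply(plan$segments, n_samples, integer(1)) == 600L))
  for (f in plan$folds) {
    expect_length(f$train, 7L)
    expect_false(f$test %in% f$train)
  }
  reduced <- build_cv_plan(scans, "fmri", reduce = "second_quarter")
  expect_length(reduced$folds, 8L)
  expect_true(all(vapply(reduced$segments, n_samples, integer(1)) == 150L))

  ieeg <- build_cv_plan(recording(matrix(rnorm(2 * 5000), 2),
                                  sampling_interval = 1 / 500), "ieeg")
  expect_length(ieeg$folds, 1L)
  expect_equal(n_samples_of <- vapply(ieeg$segments, function(s) ncol(s$values),
                                      integer(1)), c(4000L, 1000L))
  expect_error(build_cv_plan(recording(matrix(rnorm(4), 2)), "fmri"),
               class = "pembench_insufficient_samples")
})

test_that("signed-rank comparison gives exact small-sample p-values and a BH mask", {
  a <- c(5, 6, 7, 8, 9)
  b <- a - c(1, 2, 1.5, 3, 2.5)  # tie-free differences keep the test exact
  scores <- rbind(a = a, b = b)
  res <- signed_rank_compare(scores)
  expect_equal(res$p["a", "b"], 1 / 32)
  expect_equal(res$direction["a", "b"], 1)
  same <- rbind(x = a, y = a)
  res2 <- signed_rank_compare(same)
  expect_equal(res2$p["x", "y"], 1)
  expect_false(any(res2$significant, na.rm = TRUE))
  # BH monotonicity: a smaller alpha never adds discoveries
  set.seed(9)
  many <- rbind(m1 = rnorm(20), m2 = rnorm(20) + 0.5, m3 = rnorm(20) + 1)
  r_lo <- signed_rank_compare(many, alpha = 0.01)
  r_hi <- signed_rank_compare(many, alpha = 0.05)
  expect_true(all(r_hi$significant >= r_lo$significant, na.rm = TRUE))
})

test_that("evaluate_model composes scoring, whiteness and timing correctly", {
  sim <- gen_stable_var(3, d = 1, T = 2400, seed = 15)
  plan <- build_cv_plan(list(sim$recording), "fmri")
  rows <- evaluate_model("zero", plan, seed = 3)
  expect_equal(nrow(rows), 2L * 3L)
  f1 <- plan$folds[[1L]]
  ps <- predict_zero(plan$segments[[f1$test]])
  expect_equal(rows$r2[rows$fold == 1],
               unname(r2_score(ps)$r2), tolerance = 1e-12)
  expect_true(all(rows$fit_time == 0))
  mrows <- suppressWarnings(
    evaluate_model("mmse", plan, beta = 0.05, seed = 3))
  expect_true(all(mrows$fit_time == 0))
  lrows <- evaluate_model("linear", plan, d = 1, structure = "dense", seed = 3)
  expect_gt(median(lrows$r2), median(rows$r2))
})
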
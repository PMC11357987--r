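test_that("iid tanh ensembles have the stated shapes and relations", {
  ens <- gen_iid_tanh_ensemble(5, 2000, seed = 1)
  expect_equal(dim(ens$x$values), c(5L, 2000L))
  expect_equal(dim(ens$y$values), c(5L, 2000L))
  expect_length(ens$x_ave, 2000L)
  expect_identical(ens$y$values, tanh(ens$x$values))
  one <- gen_iid_tanh_ensemble(1, 500, seed = 2)
  expect_equal(one$y_ave, tanh(one$x_ave))
  expect_error(gen_iid_tanh_ensemble(0, 100, 1),
               class = "pembench_invalid_parameter")
  expect_error(gen_iid_tanh_ensemble(2, 1, 1),
               class = "pembench_invalid_parameter")
})

test_that("generators are pure functions of their seed", {
  a <- gen_iid_tanh_ensemble(3, 100, seed = 7)
  b <- gen_iid_tanh_ensemble(3, 100, seed = 7)
  expect_identical(a$x$values, b$x$values)
  c1 <- gen_colored_signal(256, 1.5, seed = 9)
  c2 <- gen_colored_signal(256, 1.5, seed = 9)
  expect_identical(c1$values, c2$values)
  v1 <- gen_stable_var(3, T = 200, seed = 5)
  v2 <- gen_stable_var(3, T = 200, seed = 5)
  expect_identical(v1$recording$values, v2$recording$values)
  s1 <- simulate_izhikevich(izhikevich_params(input_noise_std = 2),
                            2, 100, seed = 3)
  s2 <- simulate_izhikevich(izhikevich_params(input_noise_std = 2),
                            2, 100, seed = 3)
  expect_identical(s1$v, s2$v)
})

test_that("sphere ensembles realize the distance-decaying correlation", {
  ens <- gen_sphere_correlated_ensemble(50, 0.5, 5000, seed = 4)
  expect_true(all(sqrt(rowSums(ens$positions^2)) <= 1))
  D <- as.matrix(dist(ens$positions))
  C <- cor(t(ens$x$values))
  off <- upper.tri(D)
  expect_lt(mean(abs(C[off] - exp(-D[off] / 0.5))), 0.05)

  # perfectly correlated limit: all units identical, averaging preserves tanh
  inf_ens <- gen_sphere_correlated_ensemble(10, Inf, 300, seed = 5)
  expect_lt(max(abs(sweep(inf_ens$x$values, 2, inf_ens$x$values[1, ]))), 1e-12)
  expect_equal(inf_ens$y_ave, tanh(inf_ens$x_ave), tolerance = 1e-12)

  # vanishing correlation length degenerates to the iid ensemble
  tiny <- gen_sphere_correlated_ensemble(20, 1e-3, 5000, seed = 6)
  Ct <- cor(t(tiny$x$values))
  expect_lt(max(abs(Ct[upper.tri(Ct)])), 0.1)
  ks <- suppressWarnings(ks.test(as.numeric(tiny$x$values), pnorm))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the Gaussian low-pass filter has unit gain and the stated kernel", {
  x <- rnorm(100)
  expect_identical(gaussian_lpf(x, 1), x)
  expect_equal(gaussian_lpf(rep(2.5, 200), 0.1), rep(2.5, 200),
               tolerance = 1e-12)
  # white-noise variance shrinks by the sum of squared taps; the filtered
  # series is strongly autocorrelated, so average the ratio over seeds
  f <- 0.1
  sigma <- 1 / f - 1
  L <- max(1, ceiling(4 * sigma))
  taps <- dnorm(seq(-L, L), sd = sigma); taps <- taps / sum(taps)
  ratio <- mean(vapply(1:10, function(s) {
    set.seed(s)
    w <- rnorm(1e4)
    var(gaussian_lpf(w, f)) / var(w)
  }, numeric(1)))
  expect_equal(ratio, sum(taps^2), tolerance = 0.05)
  expect_error(gaussian_lpf(x, 0), class = "pembench_invalid_parameter")
  expect_error(gaussian_lpf(x, 1.5), class = "pembench_invalid_parameter")
})

test_that("colored signals have the requested spectral decay and unit variance", {
  slope_of <- function(p, seed) {
    x <- as.numeric(gen_colored_signal(2^14, p, seed)$values)
    sp <- stats::spec.pgram(stats::ts(x), plot = FALSE, taper = 0)
    keep <- sp$freq > 0.01
    unname(coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
  }
  expect_lt(abs(mean(vapply(1:5, function(s) slope_of(0, s), 0))), 0.15)
  expect_lt(abs(mean(vapply(1:10, function(s) slope_of(2, s), 0)) + 2), 0.25)
  expect_equal(var(as.numeric(gen_colored_signal(512, 3, 8)$values)), 1,
               tolerance = 1e-12)
  expect_error(gen_colored_signal(32, 1, 1),
               class = "pembench_invalid_parameter")
})

test_that("noise injection hits the requested SNR", {
  set.seed(3)
  x <- rnorm(1e4)
  noisy <- add_noise_at_snr(x, 1, seed = 21)
  expect_gt(var(noisy - x) / var(x), 0.9)
  expect_lt(var(noisy - x) / var(x), 1.1)
  expect_error(add_noise_at_snr(rep(1, 100), 2, 1),
               class = "pembench_degenerate_signal")
  expect_error(add_noise_at_snr(x, 0, 1), class = "pembench_invalid_parameter")
})

test_that("sum-tanh datasets have the stated geometry", {
  ds <- gen_sum_tanh_dataset(40, 1000, seed = 2)
  expect_equal(dim(ds$X), c(1000L, 40L))
  expect_length(ds$y, 1000L)
  one <- gen_sum_tanh_dataset(1, 100, seed = 3)
  expect_identical(one$y, tanh(as.numeric(one$X)))
  big <- gen_sum_tanh_dataset(8, 1e4, seed = 4)
  expect_equal(var(rowSums(big$X)), 8, tolerance = 0.8)
  expect_error(gen_sum_tanh_dataset(10, 11, 1),
               class = "pembench_insufficient_samples")
})

test_that("stable VAR generation hits the spectral radius and its stationary law", {
  sim <- gen_stable_var(4, d = 2, T = 500, spectral_radius_target = 0.9,
                        seed = 13)
  rho <- max(Mod(eigen(companion_matrix(sim$truth$A_list))$values))
  expect_lte(rho, 0.9 + 1e-9)
  expect_error(gen_stable_var(3, density = 0, T = 500, seed = 1),
               class = "pembench_invalid_parameter")
  expect_error(gen_stable_var(5, T = 40, seed = 1),
               class = "pembench_insufficient_samples")

  # lag-0 sample covariance vs the discrete Lyapunov solution
  big <- gen_stable_var(3, d = 1, T = 1e5, seed = 17)
  S_emp <- tcrossprod(big$recording$values - rowMeans(big$recording$values)) /
    (ncol(big$recording$values) - 1)
  S_true <- oracle_stationary_cov(big$truth$A_list, big$truth$noise_std)
  expect_lt(norm(S_emp - S_true, "F") / norm(S_true, "F"), 0.05)
})

test_that("Izhikevich integration respects its fixed point, resets, and oracle", {
  p0 <- izhikevich_params(I = 0, input_noise_std = 0)
  fx <- simulate_izhikevich(p0, 1, 50, seed = 1, v0 = -70, u0 = -14)
  expect_lt(max(abs(fx$v - (-70))), 1e-9)

  p <- izhikevich_params()  # a=0.02 b=0.2 c=-65 d=2 I=7, dt=0.1
  sim <- simulate_izhikevich(p, 1, 1000, seed = 2)
  expect_true(all(sim$v <= 30 + 1e-12))
  # reset rule: a clamped spike sample is never followed by another one
  spikes_idx <- which(sim$v[1, ] >= 30)
  expect_false(any(diff(spikes_idx) == 1))
  ref <- oracle_izhikevich_spikes(0.02, 0.2, -65, 2, 7, 0.1, 10000,
                                  v0 = -65, u0 = 0.2 * -65)
  expect_equal(length(sim$spikes[[1]]), ref)
})
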
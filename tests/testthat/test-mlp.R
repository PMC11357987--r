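pem <- asNamespace("pembench")

test_that("backpropagation matches finite differences through batch norm and dropout", {
  set.seed(42)
  cfg <- mlp_config(depth = 2, width = 4, d = 1, dropout = 0.5,
                    batchnorm = TRUE)
  params <- pem$mlp_init(3, 2, cfg)
  X <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rnorm(10), 5, 2)
  dropmask <- lapply(1:2, function(k) matrix(runif(20) >= 0.5, 5, 4))
  loss <- function(par)
    mean((pem$mlp_forward(par, X, cfg, TRUE, dropmask)$out - Y)^2)
  fw <- pem$mlp_forward(params, X, cfg, TRUE, dropmask)
  gr <- pem$mlp_backward(params, fw, X, 2 * (fw$out - Y) / length(Y),
                         cfg, dropmask)
  eps <- 1e-6
  probe <- function(setter, getter, ganal) {
    p0 <- getter(params)
    i <- which.max(abs(as.matrix(p0)))  # probe the largest-magnitude entry
    up <- as.matrix(p0); up[i] <- up[i] + eps
    dn <- as.matrix(p0); dn[i] <- dn[i] - eps
    reshape <- function(m) if (is.matrix(p0)) m else as.numeric(m)
    num <- (loss(setter(params, reshape(up))) -
              loss(setter(params, reshape(dn)))) / (2 * eps)
    expect_equal(num, as.matrix(ganal)[i], tolerance = 1e-4)
  }
  probe(function(p, v) { p$layers[[1]]$W <- v; p },
        function(p) p$layers[[1]]$W, gr$layers[[1]]$W)
  probe(function(p, v) { p$layers[[2]]$gamma <- v; p },
        function(p) p$layers[[2]]$gamma, gr$layers[[2]]$gamma)
  probe(function(p, v) { p$W_out <- v; p },
        function(p) p$W_out, gr$W_out)
})

test_that("zeroing the output layer reproduces the zero model exactly", {
  sim <- gen_stable_var(3, d = 1, T = 800, seed = 4)
  tr <- recording(sim$recording$values[, 1:600])
  te <- recording(sim$recording$values[, 601:800])
  net <- fit_mlp(tr, mlp_config(depth = 1, width = 8, epochs = 2), seed = 1)
  net$params$W_out[] <- 0
  net$params$b_out[] <- 0
  ps <- predict_mlp(net, te)   # d = 1: same alignment as the zero model
  pz <- predict_zero(te)
  expect_equal(ps$predictions, pz$predictions, tolerance = 1e-12)
})

test_that("a 10-unit block learns a chaotic quadratic map far beyond linear", {
  N <- 10000
  y <- numeric(N); y[1] <- 0.3
  for (t in 2:N) y[t] <- 1 - 2 * y[t - 1]^2
  tr <- recording(matrix(y[1:8000], 1))
  te <- recording(matrix(y[8001:N], 1))
  net <- fit_mlp(tr, mlp_config(depth = 1, width = 10, epochs = 100,
                                batch_size = 64, learning_rate = 1e-2,
                                dropout = 0), seed = 7)
  r_mlp <- r2_score(predict_mlp(net, te))$r2
  r_lin <- r2_score(predict_linear(fit_ar(tr, d = 1, structure = "dense"),
                                   te))$r2
  expect_gt(r_mlp, 0.9)
  expect_lt(r_lin, 0.7)
})

test_that("identity activations collapse the network to the dense linear model", {
  sim <- gen_stable_var(5, d = 1, T = 5000, seed = 11,
                        spectral_radius_target = 0.95)
  tr <- recording(sim$recording$values[, 1:4000])
  te <- recording(sim$recording$values[, 4001:5000])
  net <- fit_mlp(tr, mlp_config(depth = 1, width = 16,
                                activation = "identity", epochs = 60,
                                batch_size = 64, learning_rate = 5e-3),
                 seed = 8)
  r_mlp <- median(r2_score(predict_mlp(net, te))$r2)
  r_lin <- median(r2_score(predict_linear(fit_ar(tr, d = 1,
                                                 structure = "dense"),
                                          te))$r2)
  expect_lt(abs(r_mlp - r_lin), 0.05)
})

test_that("MLP training is reproducible and validates its inputs", {
  sim <- gen_stable_var(2, d = 1, T = 600, seed = 19)
  cfg <- mlp_config(depth = 1, width = 4, epochs = 3)
  n1 <- fit_mlp(sim$recording, cfg, seed = 5)
  n2 <- fit_mlp(sim$recording, cfg, seed = 5)
  expect_identical(n1$params$W_out, n2$params$W_out)
  expect_error(mlp_config(depth = 0), class = "pembench_invalid_parameter")
  expect_error(fit_mlp(recording(matrix(rnorm(20), 1)),
                       mlp_config(batch_size = 64)),
               class = "pembench_insufficient_samples")
})
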
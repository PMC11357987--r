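# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force statistics, closed forms, and a
# second, straightforward implementation of the Euler neuron loop.

# Brute-force portmanteau statistic: literal double sum over lags and the
# definition of the lagged correlation matrices.
oracle_portmanteau_q <- function(E, M) {
  n <- nrow(E); N <- ncol(E)
  R <- function(i) {
    acc <- matrix(0, n, n)
    for (t in 0:(N - M - 1)) acc <- acc + E[, t + i + 1] %*% t(E[, t + 1])
    acc / (N - M)
  }
  R0i <- MASS::ginv(R(0))
  q <- 0
  for (i in 1:M) {
    Ri <- R(i)
    q <- q + sum(diag(t(Ri) %*% R0i %*% Ri %*% R0i))
  }
  (N - M) * q
}

# Stationary covariance of a VAR via the vectorized discrete Lyapunov
# equation on the companion form: vec(S) = (I - A (x) A)^-1 vec(Qc).
oracle_stationary_cov <- function(A_list, noise_std) {
  Ac <- pembench::companion_matrix(A_list)
  n <- nrow(A_list[[1]]); d <- length(A_list)
  Qc <- matrix(0, n * d, n * d)
  Qc[1:n, 1:n] <- diag(noise_std^2, n)
  m <- nrow(Ac)
  vecS <- solve(diag(m * m) - kronecker(Ac, Ac), as.vector(Qc))
  S <- matrix(vecS, m, m)
  S[1:n, 1:n]
}

# Plain scalar-loop Euler integration of one Izhikevich neuron.
oracle_izhikevich_spikes <- function(a, b, c, d, I, dt, steps, v0, u0) {
  v <- v0; u <- u0; count <- 0L
  for (t in seq_len(steps)) {
    v_old <- v
    v <- v + dt * (0.04 * v_old^2 + 5 * v_old + 140 - u + I)
    u <- u + dt * a * (b * v_old - u)
    if (v >= 30) { count <- count + 1L; v <- c; u <- u + d }
  }
  count
}

# One-step Kalman predictor with the TRUE innovation-form matrices.
oracle_kalman_predict <- function(A, C, K, y) {
  n <- nrow(y); N <- ncol(y)
  x <- matrix(0, nrow(A), 1)
  pred <- matrix(NA_real_, n, N)
  for (t in seq_len(N)) {
    pred[, t] <- C %*% x
    x <- A %*% x + K %*% (y[, t, drop = FALSE] - C %*% x)
  }
  pred
}

r2_simple <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

# Simulate an innovation-form state-space system (truth for subspace tests).
sim_innovation_ss <- function(A, C, K, sigma_e, N, seed) {
  set.seed(seed)
  nx <- nrow(A); n <- nrow(C)
  x <- matrix(0, nx, 1)
  y <- matrix(0, n, N)
  for (t in seq_len(N)) {
    e <- matrix(rnorm(n, sd = sigma_e), n, 1)
    y[, t] <- C %*% x + e
    x <- A %*% x + K %*% e
  }
  y
}
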
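# Ground-truth dynamical generators: stable sparse first-difference VARs and
# Izhikevich spiking neurons.

#' Companion matrix of a lag polynomial
#'
#' Stacks lag coefficient matrices `A_1 ... A_d` (each n x n, acting as
#' `y(t) = sum_p A_p y(t-p) + e(t)`) into the `nd x nd` companion form whose
#' spectral radius determines stationarity.
#'
#' @param A_list list of n x n lag coefficient matrices.
#' @return companion matrix.
#' @export
companion_matrix <- function(A_list) {
  d <- length(A_list)
  n <- nrow(A_list[[1L]])
  C <- matrix(0, n * d, n * d)
  C[seq_len(n), ] <- do.call(cbind, A_list)
  if (d > 1L)
    C[n + seq_len(n * (d - 1L)), seq_len(n * (d - 1L))] <-
      diag(n * (d - 1L))
  C
}

#' Generate a stable sparse first-difference VAR and simulate it
#'
#' Ground truth for parameter-recovery tests. The model is
#' `y(t) - y(t-1) = W y(t-1) + D_2 y(t-2) + ... + D_d y(t-d) + e(t)` with a
#' sparse random drift matrix `W`, diagonal higher-lag coefficients, and iid
#' Gaussian process noise. The lag polynomial is rescaled so that the
#' companion matrix has spectral radius exactly `spectral_radius_target`
#' (scaling the lag-p coefficient by `s^p` scales every companion eigenvalue
#' by `s`). A burn-in of `10 * n` samples is simulated and discarded.
#'
#' @param n number of channels.
#' @param d model order (number of lags, >= 1).
#' @param density fraction of nonzero entries in `W`, in (0, 1].
#' @param spectral_radius_target target companion spectral radius in (0, 1).
#' @param T number of retained samples; must exceed `10 * n * d`.
#' @param noise_std process-noise standard deviation.
#' @param seed integer seed.
#' @param sampling_interval seconds per sample for the returned recording.
#' @return list with `recording` (the simulated [recording]) and `truth`
#'   (class `ground_truth_var`: `W`, `lag_diagonals`, `noise_std`,
#'   `spectral_radius_target`, and the full lag matrices `A_list`).
#' @examples
#' gt <- gen_stable_var(3, T = 400, seed = 1)
#' max(Mod(eigen(companion_matrix(gt$truth$A_list))$values))
#' @export
gen_stable_var <- function(n, d = 1L, density = 0.3,
                           spectral_radius_target = 0.9, T,
                           noise_std = 1, seed, sampling_interval = 1) {
  n <- check_count(n, "n")
  d <- check_count(d, "d")
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop_invalid("'density' must lie in (0, 1] (a zero-density lag-1 model is a random walk)")
  if (spectral_radius_target <= 0 || spectral_radius_target >= 1)
    stop_invalid("'spectral_radius_target' must lie in (0, 1)")
  T <- check_count(T, "T", min = 2L)
  if (T <= 10L * n * d)
    stop_samples(sprintf("T must exceed 10*n*d = %d for a usable simulation", 10L * n * d))
  if (noise_std <= 0) stop_invalid("'noise_std' must be positive")

  local_seed(seed, {
    mask <- matrix(runif(n * n) < density, n, n)
    if (!any(mask)) mask[sample.int(n * n, 1L)] <- TRUE
    W0 <- matrix(rnorm(n * n, sd = 1 / sqrt(n)), n, n) * mask
    A <- vector("list", d)
    A[[1L]] <- diag(n) + W0
    if (d > 1L)
      for (p in 2:d) A[[p]] <- diag(rnorm(n, sd = 0.2 / p), n, n)
    rho0 <- spectral_radius(companion_matrix(A))
    s <- spectral_radius_target / rho0
    for (p in seq_len(d)) A[[p]] <- A[[p]] * s^p

    burn <- 10L * n
    total <- T + burn + d
    y <- matrix(0, n, total)
    E <- matrix(rnorm(n * total, sd = noise_std), n, total)
    for (t in (d + 1L):total) {
      acc <- E[, t]
      for (p in seq_len(d)) acc <- acc + A[[p]] %*% y[, t - p]
      y[, t] <- acc
    }
    truth <- structure(list(
      W = A[[1L]] - diag(n),
      lag_diagonals = if (d > 1L) lapply(A[-1L], diag) else list(),
      A_list = A,
      noise_std = noise_std,
      spectral_radius_target = spectral_radius_target,
      d = d, density = density, seed = seed),
      class = "ground_truth_var")
    list(recording = recording(y[, total - T + seq_len(T), drop = FALSE],
                               sampling_interval = sampling_interval),
         truth = truth)
  })
}

#' Izhikevich neuron parameters
#'
#' Constants of the two-variable quadratic integrate-and-fire model with
#' membrane recovery: `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and
#' `du/dt = a (b v - u)`, with the reset `(v, u) <- (c, u + d)` whenever
#' `v >= 30` mV. Defaults are the regular-spiking constants with a tonic
#' driving current.
#'
#' @param a recovery time scale (1/ms).
#' @param b recovery sensitivity.
#' @param c after-spike reset potential (mV).
#' @param d after-spike recovery increment.
#' @param I tonic input current.
#' @param dt Euler step in ms (default 0.1).
#' @param input_noise_std standard deviation of independent Gaussian noise
#'   added to the input current at every step (0 = deterministic).
#' @return list of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 2, I = 7,
                              dt = 0.1, input_noise_std = 0) {
  if (dt <= 0) stop_invalid("'dt' must be positive")
  if (input_noise_std < 0) stop_invalid("'input_noise_std' must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, I = I, dt = dt,
                 v_reset_threshold = 30, input_noise_std = input_noise_std),
            class = "izhikevich_params")
}

#' Simulate uncoupled Izhikevich neurons by Euler integration
#'
#' Integrates `n_neurons` independent copies of the Izhikevich model with
#' the forward Euler scheme at step `params$dt` (0.1 ms by default). When a
#' membrane potential reaches 30 mV the recorded sample is clamped to 30, a
#' spike is logged, and the state is reset. Neurons are uncoupled; with
#' `input_noise_std > 0` each receives its own white input-current noise,
#' which desynchronizes the population.
#'
#' @param params an [izhikevich_params] object.
#' @param n_neurons number of neurons.
#' @param duration_ms simulated duration in ms (>= 10 steps).
#' @param seed integer seed.
#' @param v0,u0 initial conditions (defaults `c` and `b * c`; recycled
#'   across neurons).
#' @param random_init if `TRUE`, draw each neuron's initial membrane
#'   potential uniformly between `c` and the spike threshold (random
#'   phases), modelling an asynchronous population rather than one started
#'   in lockstep.
#' @return list with `v` (`n_neurons` x steps membrane potentials), `u`
#'   (final recovery states), `spikes` (list of spike-time vectors, ms),
#'   `time_ms`, and `params`.
#' @export
simulate_izhikevich <- function(params = izhikevich_params(), n_neurons = 1L,
                                duration_ms, seed = 1L,
                                v0 = params$c, u0 = params$b * v0,
                                random_init = FALSE) {
  stopifnot(inherits(params, "izhikevich_params"))
  n_neurons <- check_count(n_neurons, "n_neurons")
  if (duration_ms < 10 * params$dt)
    stop_invalid("'duration_ms' must cover at least 10 integration steps")
  steps <- as.integer(floor(duration_ms / params$dt))
  local_seed(seed, {
    v <- if (random_init)
      runif(n_neurons, params$c, params$v_reset_threshold) else
      rep(v0, length.out = n_neurons)
    u <- if (random_init) params$b * v else rep(u0, length.out = n_neurons)
    V <- matrix(NA_real_, n_neurons, steps)
    spikes <- vector("list", n_neurons)
    noisy <- params$input_noise_std > 0
    for (t in seq_len(steps)) {
      I_t <- params$I
      if (noisy) I_t <- I_t + rnorm(n_neurons, sd = params$input_noise_std)
      dv <- 0.04 * v^2 + 5 * v + 140 - u + I_t
      du <- params$a * (params$b * v - u)
      v <- v + params$dt * dv
      u <- u + params$dt * du
      if (any(!is.finite(v)) || any(!is.finite(u)))
        pem_stop(sprintf("Izhikevich integration blew up at step %d", t),
                 "pembench_integration_failure")
      fired <- v >= params$v_reset_threshold
      if (any(fired)) {
        V[fired, t] <- params$v_reset_threshold
        for (i in which(fired))
          spikes[[i]] <- c(spikes[[i]], t * params$dt)
        v[fired] <- params$c
        u[fired] <- u[fired] + params$d
      }
      V[!fired, t] <- v[!fired]
    }
    list(v = V, u = u, spikes = spikes,
         time_ms = seq_len(steps) * params$dt, params = params)
  })
}
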
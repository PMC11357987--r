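# Generators for the static (non-dynamical) simulation suite: ensembles of
# (x, tanh(x)) pairs, distance-correlated fields on a unit sphere, power-law
# signals, Gaussian low-pass filtering, and noise injection at fixed SNR.

signal_ensemble <- function(values, kind, params, seed) {
  structure(list(values = values, kind = kind, params = params, seed = seed),
            class = "signal_ensemble")
}

#' @export
print.signal_ensemble <- function(x, ...) {
  cat(sprintf("<signal_ensemble '%s'> %d unit(s) x %d samples (seed %g)\n",
              x$kind, nrow(x$values), ncol(x$values), x$seed))
  invisible(x)
}

#' Independent (x, tanh(x)) signal pairs and their spatial averages
#'
#' Draws `n_ave` independent unit signals `x_i(t)` as iid standard normals,
#' sets `y_i(t) = tanh(x_i(t))`, and returns both ensembles together with
#' their across-unit arithmetic means. The mean pair `(x_ave, y_ave)` is the
#' object whose linear-vs-nonlinear predictability the spatial-averaging
#' experiment tracks: each individual pair is exactly sigmoidal, while
#' averaging over even a handful of independent units renders the relation
#' between the averages effectively linear.
#'
#' @param n_ave number of averaged unit pairs (>= 1).
#' @param T number of time samples (>= 2).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and seed.
#' @return list with `x`, `y` (`signal_ensemble`s of size `n_ave` x `T`) and
#'   the length-`T` averages `x_ave`, `y_ave`.
#' @examples
#' ens <- gen_iid_tanh_ensemble(5, 200, seed = 1)
#' cor(ens$x_ave, ens$y_ave)
#' @export
gen_iid_tanh_ensemble <- function(n_ave, T, seed) {
  n_ave <- check_count(n_ave, "n_ave")
  T <- check_count(T, "T", min = 2L)
  x <- local_seed(seed, matrix(rnorm(n_ave * T), n_ave, T))
  y <- tanh(x)
  list(x = signal_ensemble(x, "iid_tanh", list(n_ave = n_ave, T = T), seed),
       y = signal_ensemble(y, "iid_tanh", list(n_ave = n_ave, T = T), seed),
       x_ave = colMeans(x), y_ave = colMeans(y))
}

#' Distance-correlated (x, tanh(x)) pairs on a unit sphere
#'
#' Places `n_ave` units uniformly at random inside the unit ball and draws
#' jointly Gaussian unit signals whose pairwise correlation decays
#' exponentially with Euclidean distance, `corr(x_i, x_j) =
#' exp(-dist_ij / corr_length)`. `y = tanh(x)` elementwise.
#' `corr_length = Inf` makes all units copies of one signal (perfect
#' correlation), in which case averaging preserves the sigmoidal relation
#' exactly; any finite correlation length lets averaging wash it out.
#'
#' @param n_ave number of units.
#' @param corr_length correlation length (positive; may be `Inf`).
#' @param T number of samples.
#' @param seed integer seed.
#' @return as [gen_iid_tanh_ensemble], plus `positions` (`n_ave` x 3).
#' @export
gen_sphere_correlated_ensemble <- function(n_ave, corr_length, T, seed) {
  n_ave <- check_count(n_ave, "n_ave")
  T <- check_count(T, "T", min = 2L)
  if (!is.numeric(corr_length) || length(corr_length) != 1L ||
      is.na(corr_length) || corr_length <= 0)
    stop_invalid("'corr_length' must be positive (possibly Inf)")
  out <- local_seed(seed, {
    # uniform in the unit ball: random direction, radius ~ u^(1/3)
    dir <- matrix(rnorm(3 * n_ave), n_ave, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pos <- dir * runif(n_ave)^(1 / 3)
    z <- matrix(rnorm(n_ave * T), n_ave, T)
    if (is.infinite(corr_length)) {
      x <- matrix(rep(z[1L, ], each = n_ave), n_ave, T)
    } else {
      D <- as.matrix(stats::dist(pos))
      C <- exp(-D / corr_length)
      L <- NULL
      for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
        L <- tryCatch(chol(C + diag(jit, n_ave)), error = function(e) NULL)
        if (!is.null(L)) break
      }
      if (is.null(L))
        stop_numeric("covariance factorization failed even after jitter escalation")
      x <- crossprod(L, z)
    }
    list(x = x, pos = pos)
  })
  y <- tanh(out$x)
  params <- list(n_ave = n_ave, corr_length = corr_length, T = T)
  list(x = signal_ensemble(out$x, "sphere", params, seed),
       y = signal_ensemble(y, "sphere", params, seed),
       x_ave = colMeans(out$x), y_ave = colMeans(y),
       positions = out$pos)
}

#' Gaussian low-pass filter
#'
#' Convolves each time series with a unit-sum discrete Gaussian kernel whose
#' standard deviation is `1/f_cutoff - 1` samples, truncated at four standard
#' deviations, with reflective boundary handling. `f_cutoff` is interpreted
#' as a cutoff normalized to the Nyquist frequency, so `f_cutoff = 1` applies
#' no filtering and returns the input unchanged.
#'
#' @param series numeric vector, or matrix with time along columns.
#' @param f_cutoff cutoff in (0, 1].
#' @return filtered series with the shape of the input.
#' @examples
#' identical(gaussian_lpf(1:10, 1), as.numeric(1:10))
#' @export
gaussian_lpf <- function(series, f_cutoff) {
  if (!is.numeric(f_cutoff) || length(f_cutoff) != 1L ||
      !is.finite(f_cutoff) || f_cutoff <= 0 || f_cutoff > 1)
    stop_invalid("'f_cutoff' must lie in (0, 1]")
  vec <- !is.matrix(series)
  m <- if (vec) matrix(as.numeric(series), nrow = 1L) else series
  if (ncol(m) < 2L) stop_samples("series length must be >= 2")
  sigma <- 1 / f_cutoff - 1
  if (sigma == 0) return(series)
  L <- max(1L, ceiling(4 * sigma))
  taps <- dnorm(seq(-L, L), sd = sigma)
  taps <- taps / sum(taps)
  Tn <- ncol(m)
  # mirror boundary: position p maps to a reflected in-range index
  p <- (1L - L):(Tn + L)
  q <- (p - 1L) %% (2L * (Tn - 1L))
  idx <- ifelse(q < Tn, q + 1L, 2L * Tn - 1L - q)
  out <- t(apply(m[, idx, drop = FALSE], 1L, function(r)
    stats::filter(r, taps, sides = 2L)))
  out <- out[, L + seq_len(Tn), drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Power-law (1/f^p) signal by spectral synthesis
#'
#' Builds a length-`T` signal whose power spectral density decays as
#' `(1 + k)^(-p)` over the discrete frequency index `k` (finite amplitude at
#' DC), with uniformly random phases, then rescales to unit sample variance.
#' `p = 0` gives white noise; larger `p` gives progressively redder signals.
#'
#' @param T number of samples (>= 64).
#' @param p nonnegative spectral decay exponent.
#' @param seed integer seed.
#' @return a `signal_ensemble` with one unit.
#' @export
gen_colored_signal <- function(T, p, seed) {
  T <- check_count(T, "T", min = 64L)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0)
    stop_invalid("'p' must be a nonnegative real")
  x <- local_seed(seed, {
    half <- T %/% 2L
    k <- 0:half
    amp <- (1 + k)^(-p / 2)
    phase <- runif(half + 1L, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    # DC (and Nyquist for even T) must be real
    spec[1L] <- amp[1L] * cos(phase[1L])
    if (T %% 2L == 0L) spec[half + 1L] <- amp[half + 1L] * cos(phase[half + 1L])
    full <- c(spec, Conj(rev(spec[2:(half + (T %% 2L == 1L))])))
    full <- full[seq_len(T)]
    Re(fft(full, inverse = TRUE)) / T
  })
  x <- x / sd(x)
  signal_ensemble(matrix(x, 1L), "colored", list(T = T, p = p), seed)
}

#' Add independent Gaussian noise at a prescribed SNR
#'
#' SNR is defined as signal variance divided by noise variance. Noise is
#' zero-mean Gaussian, generated independently of the signal, with variance
#' `var(series)/snr` (per channel for matrix input).
#'
#' @param series numeric vector or channels-by-time matrix with positive
#'   variance.
#' @param snr positive signal-to-noise variance ratio.
#' @param seed integer seed.
#' @return noisy series with the shape of the input.
#' @export
add_noise_at_snr <- function(series, snr, seed) {
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0)
    stop_invalid("'snr' must be a single positive number")
  vec <- !is.matrix(series)
  m <- if (vec) matrix(as.numeric(series), nrow = 1L) else series
  v <- apply(m, 1L, var)
  if (any(v <= 0))
    stop_degenerate("zero-variance series: SNR is undefined")
  noise <- local_seed(seed,
    matrix(rnorm(length(m)), nrow(m)) * sqrt(v / snr))
  out <- m + noise
  if (vec) as.numeric(out) else out
}

#' High-dimensional one-dimensional nonlinearity: y = tanh(x1 + ... + xn)
#'
#' Draws `N` samples of `n` iid standard-normal predictors and the noise-free
#' response `tanh` of their row sums. The response depends on a single
#' direction in predictor space, so the relation is a one-dimensional
#' sigmoid embedded in `n + 1` dimensions; with a fixed sample budget its
#' learnability by local methods degrades as `n` grows.
#'
#' @param n number of predictors.
#' @param N number of samples (must exceed `n + 1`).
#' @param seed integer seed.
#' @return list with `X` (`N` x `n`) and `y` (length `N`).
#' @export
gen_sum_tanh_dataset <- function(n, N, seed) {
  n <- check_count(n, "n")
  N <- check_count(N, "N")
  if (N <= n + 1L)
    stop_samples(sprintf("N = %d samples cannot constrain n = %d dimensions", N, n))
  X <- local_seed(seed, matrix(rnorm(N * n), N, n))
  list(X = X, y = tanh(rowSums(X)))
}
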
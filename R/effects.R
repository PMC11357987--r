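# Drivers for the linearizing-mechanism experiments: spatial averaging,
# distance-correlated averaging, temporal averaging (low-pass filtering of
# colored signals), observation noise, sample-limited dimensionality, and
# population averaging of spiking neurons. Each reports a grid of
# linear-vs-optimal-nonlinear cross-validated R^2 values.

effect_curve <- function(grid, r2_lin, r2_nl, param, reps, seeds,
                         optimal_h = NULL) {
  # r2_lin / r2_nl: reps x length(grid) matrices
  se <- function(m) apply(m, 2L, sd) / sqrt(nrow(m))
  df <- data.frame(grid = grid,
                   r2_linear = colMeans(r2_lin),
                   r2_linear_se = se(r2_lin),
                   r2_nonlinear = colMeans(r2_nl),
                   r2_nonlinear_se = se(r2_nl),
                   gap = colMeans(r2_nl - r2_lin),
                   gap_se = se(r2_nl - r2_lin))
  structure(list(table = df, param = param, reps = reps, seeds = seeds,
                 optimal_h = optimal_h,
                 r2_linear = r2_lin, r2_nonlinear = r2_nl),
            class = "effect_curve")
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(sprintf("<effect_curve over '%s'> (%d repetition(s) per point)\n",
              x$param, x$reps))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.effect_curve <- function(x, ...) {
  tab <- x$table
  graphics::matplot(tab$grid, cbind(tab$r2_linear, tab$r2_nonlinear),
                    type = "b", pch = c(1, 16), lty = 1,
                    col = c("forestgreen", "goldenrod"),
                    xlab = x$param, ylab = expression(R^2), log = "x", ...)
  graphics::legend("bottomright", c("linear", "nonlinear"),
                   col = c("forestgreen", "goldenrod"), pch = c(1, 16))
  invisible(x)
}

# Contiguous k-fold cross-validated R^2 of linear regression and a supplied
# nonlinear regressor on a static (x, y) relation. Returns c(lin, nl).
cv_static_gap <- function(x, y, k = 2L, nonlinear) {
  x <- as.matrix(x)
  N <- length(y)
  bounds <- floor(seq(0L, N, length.out = k + 1L))
  rl <- rn <- numeric(k)
  for (f in seq_len(k)) {
    te <- (bounds[f] + 1L):bounds[f + 1L]
    tr <- setdiff(seq_len(N), te)
    cf <- qr.coef(qr(cbind(1, x[tr, , drop = FALSE])), y[tr])
    cf[is.na(cf)] <- 0
    pl <- cbind(1, x[te, , drop = FALSE]) %*% cf
    rl[f] <- r2_per_channel(y[te], as.numeric(pl))$r2
    rn[f] <- r2_per_channel(y[te], nonlinear(x[tr, , drop = FALSE], y[tr],
                                             x[te, , drop = FALSE]))$r2
  }
  c(mean(rl), mean(rn))
}

run_effect <- function(grid, reps, seed, param, fun) {
  if (!length(grid)) stop_invalid("grid must be nonempty")
  seeds <- derive_seeds(seed, reps)
  r2_lin <- matrix(NA_real_, reps, length(grid))
  r2_nl <- matrix(NA_real_, reps, length(grid))
  extras <- matrix(NA_real_, reps, length(grid))
  for (g in seq_along(grid)) for (r in seq_len(reps)) {
    res <- fun(grid[g], seeds[r])
    r2_lin[r, g] <- res[1L]; r2_nl[r, g] <- res[2L]
    if (length(res) > 2L) extras[r, g] <- res[3L]
  }
  effect_curve(grid, r2_lin, r2_nl, param, reps, seeds,
               optimal_h = if (any(is.finite(extras))) colMeans(extras))
}

#' Spatial-averaging experiment
#'
#' For each grid value `N_ave`, generates `N_ave` independent
#' `(x, tanh(x))` signal pairs of length `T`, averages each ensemble across
#' units, and scores 2-fold cross-validated R-squared of linear regression
#' against the MMSE (weighted-histogram conditional-mean) regressor for
#' predicting the y-average from the x-average. Linear and nonlinear
#' predictors see identical data within each repetition (paired seeds).
#'
#' @param n_ave_grid increasing grid of averaged-pair counts.
#' @param T samples per signal.
#' @param reps repetitions (independent seeds) per grid point.
#' @param seed root seed.
#' @param beta,n_bins MMSE regressor settings.
#' @return an `effect_curve`.
#' @export
spatial_averaging_curve <- function(n_ave_grid = c(1, 2, 3, 5, 8, 10, 20),
                                    T = 2000L, reps = 20L, seed = 1L,
                                    beta = 0.02, n_bins = 100L) {
  run_effect(n_ave_grid, reps, seed, "N_ave", function(nav, s) {
    ens <- gen_iid_tanh_ensemble(nav, T, s)
    cv_static_gap(ens$x_ave, ens$y_ave, 2L, function(xtr, ytr, xte)
      mmse_regression(xtr, ytr, xte, beta, n_bins))
  })
}

#' Spatial averaging under distance-decaying correlation
#'
#' As [spatial_averaging_curve] but with units placed in a unit sphere and
#' correlated with correlation length `corr_length`; returns one curve over
#' `n_ave_grid` per correlation length. Perfectly correlated units
#' (`corr_length = Inf`) preserve the sigmoidal relation under averaging;
#' any finite correlation length lets the nonlinear advantage decay with
#' the number of averaged units.
#'
#' @param corr_length_grid correlation lengths (may include `Inf`).
#' @param n_ave_grid averaged-unit grid.
#' @inheritParams spatial_averaging_curve
#' @return named list of `effect_curve`s, one per correlation length.
#' @export
sphere_averaging_curve <- function(corr_length_grid = c(0.1, 0.5, 10, Inf),
                                   n_ave_grid = c(1, 5, 20),
                                   T = 2000L, reps = 10L, seed = 1L,
                                   beta = 0.02, n_bins = 100L) {
  out <- lapply(corr_length_grid, function(cl)
    run_effect(n_ave_grid, reps, seed, "N_ave", function(nav, s) {
      ens <- gen_sphere_correlated_ensemble(nav, cl, T, s)
      cv_static_gap(ens$x_ave, ens$y_ave, 2L, function(xtr, ytr, xte)
        mmse_regression(xtr, ytr, xte, beta, n_bins))
    }))
  names(out) <- paste0("corr_length=", corr_length_grid)
  out
}

#' Temporal-averaging experiment
#'
#' For each spectral decay rate `p` and cutoff `f_cutoff`, generates a
#' power-law signal `x`, sets `y = tanh(x)`, low-pass filters both with a
#' Gaussian kernel, and scores linear vs MMSE cross-validated R-squared on
#' the filtered pair. Temporal averaging (smaller cutoffs) erases the
#' nonlinear advantage, and does so at smaller cutoffs for redder signals.
#'
#' @param f_cutoff_grid Nyquist-normalized cutoffs in (0, 1], decreasing.
#' @param p_grid spectral decay exponents.
#' @inheritParams spatial_averaging_curve
#' @return named list of `effect_curve`s over `f_cutoff`, one per `p`.
#' @export
temporal_averaging_curve <- function(f_cutoff_grid = c(1, 0.5, 0.2, 0.1, 0.05, 0.02),
                                     p_grid = c(0, 1, 2, 3),
                                     T = 2000L, reps = 20L, seed = 1L,
                                     beta = 0.02, n_bins = 100L) {
  out <- lapply(p_grid, function(p)
    run_effect(f_cutoff_grid, reps, seed, "f_cutoff", function(fc, s) {
      x <- as.numeric(gen_colored_signal(T, p, s)$values)
      y <- tanh(x)
      xf <- gaussian_lpf(x, fc); yf <- gaussian_lpf(y, fc)
      cv_static_gap(xf, yf, 2L, function(xtr, ytr, xte)
        mmse_regression(xtr, ytr, xte, beta, n_bins))
    }))
  names(out) <- paste0("p=", p_grid)
  out
}

#' Observation-noise (SNR) experiment
#'
#' `x` is iid standard normal and `y = tanh(x)`; independent Gaussian noise
#' is added to both at the grid SNR (signal-to-noise variance ratio). The
#' MMSE window widens with noise as `beta = 0.02 + 0.02/SNR`. Low SNR masks
#' the sigmoidal relation entirely.
#'
#' @param snr_grid increasing SNR grid.
#' @inheritParams spatial_averaging_curve
#' @return an `effect_curve`.
#' @export
snr_curve <- function(snr_grid = c(0.25, 0.5, 1, 2, 4, 8, 100),
                      T = 2000L, reps = 20L, seed = 1L, n_bins = 100L) {
  run_effect(snr_grid, reps, seed, "SNR", function(snr, s) {
    sub <- derive_seeds(s, 3L)
    x <- local_seed(sub[1L], rnorm(T))
    y <- tanh(x)
    xn <- add_noise_at_snr(x, snr, sub[2L])
    yn <- add_noise_at_snr(y, snr, sub[3L])
    cv_static_gap(xn, yn, 2L, function(xtr, ytr, xte)
      mmse_regression(xtr, ytr, xte, beta = 0.02 + 0.02 / snr, n_bins))
  })
}

#' Dimensionality experiment
#'
#' For each input dimension `n`, draws `N` samples of the one-dimensional
#' nonlinearity `y = tanh(x_1 + ... + x_n)` (no noise, no averaging) and
#' scores 5-fold cross-validated R-squared of linear regression against the
#' locally linear predictor with its Gaussian bandwidth swept over
#' `h_grid`; the best bandwidth per fold is kept and its mean recorded.
#' With a fixed sample budget the local model is forced to larger windows
#' as `n` grows, degrading to the global linear model.
#'
#' @param n_grid input dimensions.
#' @param N samples per dataset.
#' @param h_grid bandwidth sweep (default logarithmic from 0.1 to 10).
#' @param reps repetitions per grid point.
#' @param seed root seed.
#' @return an `effect_curve` with an `optimal_h` component (mean chosen
#'   bandwidth per grid point).
#' @export
dimensionality_curve <- function(n_grid = c(1, 5, 10, 20, 40), N = 1000L,
                                 h_grid = exp(seq(log(0.1), log(10),
                                                  length.out = 12L)),
                                 reps = 10L, seed = 1L) {
  run_effect(n_grid, reps, seed, "n", function(n, s) {
    ds <- gen_sum_tanh_dataset(n, N, s)
    k <- 5L
    bounds <- floor(seq(0L, N, length.out = k + 1L))
    rl <- rn <- hstar <- numeric(k)
    for (f in seq_len(k)) {
      te <- (bounds[f] + 1L):bounds[f + 1L]
      tr <- setdiff(seq_len(N), te)
      cf <- qr.coef(qr(cbind(1, ds$X[tr, , drop = FALSE])), ds$y[tr])
      cf[is.na(cf)] <- 0
      rl[f] <- r2_per_channel(ds$y[te],
                              as.numeric(cbind(1, ds$X[te, , drop = FALSE]) %*% cf))$r2
      P <- local_linear_regression(ds$X[tr, , drop = FALSE], ds$y[tr],
                                   ds$X[te, , drop = FALSE], h_grid)
      P <- matrix(P, nrow = length(te))
      r2s <- apply(P, 2L, function(p) r2_per_channel(ds$y[te], p)$r2)
      best <- which.max(r2s)  # ties: which.max keeps the smallest grid value
      rn[f] <- r2s[best]
      hstar[f] <- h_grid[best]
    }
    c(mean(rl), mean(rn), mean(hstar))
  })
}

#' Population averaging of spiking neurons
#'
#' Simulates `n_ave` uncoupled Izhikevich neurons with independent input
#' noise, averages the membrane potential across neurons, bins it at
#' `bin_ms`, and scores a scalar linear AR-1 one-step predictor against the
#' scalar MMSE predictor by 2-fold (first half / second half) one-step
#' cross-validation on the averaged trace. The nonlinear advantage present
#' for a single neuron shrinks as the population average washes out the
#' spike-reset nonlinearity.
#'
#' @param n_ave_grid neuron-count grid.
#' @param params an [izhikevich_params] (noise std should be positive so
#'   neurons desynchronize).
#' @param duration_ms simulated duration per repetition.
#' @param bin_ms bin width for temporal averaging of the 0.1 ms trace.
#' @param reps repetitions.
#' @param seed root seed.
#' @param beta,n_bins MMSE settings.
#' @return an `effect_curve`.
#' @export
izhikevich_averaging <- function(n_ave_grid = c(1, 10, 100, 1000),
                                 params = izhikevich_params(input_noise_std = 3),
                                 duration_ms = 2000, bin_ms = 1,
                                 reps = 10L, seed = 1L,
                                 beta = 0.05, n_bins = 100L) {
  run_effect(n_ave_grid, reps, seed, "N_ave", function(nav, s) {
    sim <- simulate_izhikevich(params, n_neurons = nav,
                               duration_ms = duration_ms, seed = s,
                               random_init = TRUE)
    ave <- colMeans(sim$v)
    per_bin <- max(1L, round(bin_ms / params$dt))
    nb <- floor(length(ave) / per_bin)
    binned <- colMeans(matrix(ave[seq_len(nb * per_bin)], per_bin))
    rec <- recording(matrix(binned, 1L), sampling_interval = bin_ms / 1000)
    half <- floor(nb / 2)
    splits <- list(list(tr = seq_len(half), te = half + seq_len(nb - half)),
                   list(tr = half + seq_len(nb - half), te = seq_len(half)))
    rl <- rn <- numeric(2L)
    for (f in 1:2) {
      tr <- recording(rec$values[, splits[[f]]$tr, drop = FALSE],
                      rec$sampling_interval)
      te <- recording(rec$values[, splits[[f]]$te, drop = FALSE],
                      rec$sampling_interval)
      lin <- fit_ar(tr, d = 1L, structure = "scalar")
      rl[f] <- r2_score(predict_linear(lin, te))$r2
      mm <- mmse_predict(tr, te, mmse_config(beta = beta, n_bins = n_bins,
                                             mode = "scalar", d = 1L))
      rn[f] <- r2_score(mm)$r2
    }
    c(mean(rl), mean(rn))
  })
}

#' Grid value at which the nonlinear advantage vanishes
#'
#' Scans an effect curve for the first (smallest, or largest when
#' `direction = "largest"`) grid value whose mean nonlinear-minus-linear
#' R-squared gap falls below `epsilon`.
#'
#' @param curve an `effect_curve`.
#' @param epsilon gap threshold (> 0); default 0.01.
#' @param direction `"smallest"` or `"largest"`.
#' @return the qualifying grid value, or `NA` if none qualifies.
#' @export
gap_threshold <- function(curve, epsilon = 0.01,
                          direction = c("smallest", "largest")) {
  direction <- match.arg(direction)
  stopifnot(inherits(curve, "effect_curve"))
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop_invalid("'epsilon' must be positive")
  hit <- which(curve$table$gap < epsilon)
  if (!length(hit)) return(NA_real_)
  idx <- if (direction == "smallest") min(hit) else max(hit)
  curve$table$grid[idx]
}
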
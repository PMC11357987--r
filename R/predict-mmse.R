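# Conditional-expectation (MMSE) predictor estimated by Gaussian-windowed
# weighted histograms. For each test query, training points are weighted by
# a Gaussian in the conditioning variable (sd = beta * training range), the
# training first differences are histogrammed into n_bins equal bins with
# those weights, the histogram is normalized to a conditional distribution,
# and the prediction is its mean. Being the conditional expectation, this is
# the minimum-mean-squared-error predictor among all functions of the
# conditioning variables; on jointly Gaussian data it coincides with the
# linear predictor.

#' MMSE predictor configuration
#'
#' @param beta Gaussian window width as a fraction of the training range of
#'   the conditioning variable (sd = beta * range).
#' @param n_bins number of histogram bins (>= 2).
#' @param mode `"pairwise"` conditions the first difference of channel `i`
#'   on `y_j(t-1)` for a designated source channel `j`; `"scalar"`
#'   conditions on `d` own lags with Euclidean distance.
#' @param d lag depth for scalar mode.
#' @param pairs integer vector mapping each target channel to its
#'   conditioning source channel (pairwise mode; default: own channel).
#' @return list of class `mmse_config`.
#' @export
mmse_config <- function(beta = 0.02, n_bins = 100L,
                        mode = c("pairwise", "scalar"), d = 1L,
                        pairs = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop_invalid("'beta' must be a single positive number")
  structure(list(beta = beta, n_bins = check_count(n_bins, "n_bins", 2L),
                 mode = match.arg(mode), d = check_count(d, "d"),
                 pairs = pairs),
            class = "mmse_config")
}

# Core kernel: weighted-histogram conditional mean.
#   cond_tr: m_tr x q conditioning matrix; target_tr: m_tr target values;
#   cond_te: m_te x q queries. sigma: Gaussian sd. Histogram over
#   bin_range (length 2) with n_bins bins. Chunked over test rows.
weighted_hist_cond_mean <- function(cond_tr, target_tr, cond_te, sigma,
                                    n_bins, bin_range, chunk = 1024L) {
  lo <- bin_range[1L]; hi <- bin_range[2L]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop_degenerate("degenerate histogram range for the training differences")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  bin <- pmin(pmax(findInterval(target_tr, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  B <- matrix(0, length(target_tr), n_bins)
  B[cbind(seq_along(bin), bin)] <- 1
  m_te <- nrow(cond_te)
  pred <- numeric(m_te)
  fallback <- FALSE
  unc <- mean(target_tr)
  for (start in seq(1L, m_te, by = chunk)) {
    rows <- start:min(start + chunk - 1L, m_te)
    # squared distances in the conditioning space
    d2 <- outer(rowSums(cond_te[rows, , drop = FALSE]^2),
                rowSums(cond_tr^2), "+") -
      2 * tcrossprod(cond_te[rows, , drop = FALSE], cond_tr)
    W <- exp(-pmax(d2, 0) / (2 * sigma^2))
    Hmass <- W %*% B
    tot <- rowSums(Hmass)
    p <- as.numeric(Hmass %*% centers) / tot
    bad <- !is.finite(p)
    if (any(bad)) { p[bad] <- unc; fallback <- TRUE }
    pred[rows] <- p
  }
  if (fallback)
    warning("all histogram mass was zero for some queries; used the unconditional mean difference")
  pred
}

#' MMSE (conditional-mean) one-step-ahead prediction
#'
#' Pairwise mode predicts each channel's first difference from a single
#' conditioning channel at the previous sample; scalar mode conditions each
#' channel on `d` of its own lags. The Gaussian window sd is
#' `beta * (training range of the conditioning values)`; the histogram range
#' is the training range of the first differences. Model on demand: fit time
#' is defined as zero.
#'
#' @param train training [recording], matrix, or list of segments.
#' @param test test [recording] or matrix.
#' @param config an [mmse_config].
#' @return a [prediction_set] for `t = d+1, ..., N` (`d = 1` in pairwise
#'   mode).
#' @export
mmse_predict <- function(train, test, config) {
  stopifnot(inherits(config, "mmse_config"))
  segments <- as_segments(train)
  test <- as_segments(test)[[1L]]
  assert_clean(c(segments, list(test)))
  n <- n_channels(test)
  d <- if (config$mode == "pairwise") 1L else config$d
  qs <- lag_queries(segments, d)
  y <- test$values
  N <- ncol(y)
  if (N <= d) stop_samples("test segment shorter than the lag depth")
  t0 <- proc.time()[["elapsed"]]
  tq <- lag_queries(list(test), d)
  tt <- (d + 1L):N
  pred <- matrix(NA_real_, n, length(tt))
  if (config$mode == "pairwise") {
    pairs <- if (is.null(config$pairs)) seq_len(n) else as.integer(config$pairs)
    if (length(pairs) != n || any(pairs < 1L | pairs > n))
      stop_invalid("'pairs' must map every target channel to a source channel")
    src_rng <- range(qs$X[, unique(pairs), drop = FALSE])
    if (diff(src_rng) <= 0)
      stop_degenerate("zero training range of the conditioning variable")
    sigma <- config$beta * diff(src_rng)
    dy_rng <- range(qs$DY)
    for (i in seq_len(n)) {
      j <- pairs[i]
      pred[i, ] <- weighted_hist_cond_mean(
        qs$X[, j, drop = FALSE], qs$DY[, i],
        tq$X[, j, drop = FALSE], sigma, config$n_bins, dy_rng)
    }
  } else {
    for (i in seq_len(n)) {
      cols <- (seq_len(d) - 1L) * n + i   # own-channel lags 1..d
      ctr <- qs$X[, cols, drop = FALSE]
      rng <- range(ctr)
      if (diff(rng) <= 0)
        stop_degenerate("zero training range of the conditioning variable")
      sigma <- config$beta * diff(rng)
      pred[i, ] <- weighted_hist_cond_mean(
        ctr, qs$DY[, i], tq$X[, cols, drop = FALSE],
        sigma, config$n_bins, range(qs$DY[, i]))
    }
  }
  pred <- y[, tt - 1L, drop = FALSE] + pred
  prediction_set(pred, y[, tt, drop = FALSE], indices = tt,
                 family = sprintf("mmse-%s", config$mode),
                 fit_time = 0,
                 predict_time = proc.time()[["elapsed"]] - t0)
}

#' Static MMSE regression (weighted-histogram conditional mean)
#'
#' Estimates `E[y | x]` at the test points: Gaussian weights in `x` with
#' sd `beta * range(x_train)`, weighted histogram of `y_train` over its
#' training range with `n_bins` bins, normalized, mean taken. Used by the
#' linearizing-effects experiments where the relation of interest is a
#' static map rather than a dynamical one-step prediction.
#'
#' @param x_train,y_train training pairs (x may be a matrix; Euclidean
#'   distance is used in the multivariate case).
#' @param x_test query points.
#' @param beta Gaussian window width as a fraction of the training range.
#' @param n_bins number of histogram bins.
#' @return vector of conditional-mean predictions.
#' @export
mmse_regression <- function(x_train, y_train, x_test, beta = 0.02,
                            n_bins = 100L) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  n_bins <- check_count(n_bins, "n_bins", 2L)
  rng <- range(x_train)
  if (diff(rng) <= 0) stop_degenerate("zero training range of x")
  sigma <- beta * diff(rng)
  weighted_hist_cond_mean(x_train, as.numeric(y_train), x_test, sigma,
                          n_bins, range(y_train))
}
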
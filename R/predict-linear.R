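# Linear first-difference (V)AR models with optional LASSO sparsity.
#
# Model: y(t) - y(t-1) = W y(t-1) + D_2 y(t-2) + ... + D_d y(t-d) + e(t)
# W is the effective-connectivity matrix (dense, LASSO-sparse, or diagonal
# in the fully decoupled "scalar" mode); higher-lag coefficients are
# diagonal in AR mode and full matrices in VAR mode.

# Build the per-segment regression rows for one target channel layout.
# Returns the shared design matrix X (rows = usable time points across all
# segments) and the n-column response matrix of first differences.
build_ar_design <- function(segments, d, structure, lag_mode) {
  n <- n_channels(segments[[1L]])
  Xs <- list(); Ys <- list()
  for (seg in segments) {
    y <- seg$values
    N <- ncol(y)
    if (N <= d)
      stop_samples(sprintf("segment of length %d cannot support order d = %d", N, d))
    mu <- rowMeans(y)
    yc <- y - mu
    tt <- (d + 1L):N
    X1 <- t(yc[, tt - 1L, drop = FALSE])                 # lag-1, all channels
    lag_blocks <- if (d > 1L)
      lapply(2:d, function(p) t(yc[, tt - p, drop = FALSE])) else list()
    Xs[[length(Xs) + 1L]] <- cbind(X1, do.call(cbind, lag_blocks))
    Ys[[length(Ys) + 1L]] <- t(y[, tt, drop = FALSE] - y[, tt - 1L, drop = FALSE])
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys), n = n)
}

#' Fit a linear first-difference (V)AR model
#'
#' Minimizes, per channel, the squared one-step prediction error of
#' `y(t) - y(t-1) = W y(t-1) + sum_p D_p y(t-p) + e(t)` plus
#' `lambda` times the 1-norm of the coefficients (LASSO; coordinate descent
#' via glmnet with internal standardization, coefficients returned on the
#' original scale). Channels are mean-centered per training segment; the
#' pooled training mean is stored on the model and reapplied at prediction.
#' Lags never cross segment boundaries.
#'
#' @param train a [recording], matrix, or list of segments.
#' @param d model order (>= 1).
#' @param structure `"dense"` (unpenalized), `"sparse"` (LASSO on `W` and
#'   the lag coefficients), or `"scalar"` (`W` and all lag matrices
#'   diagonal: n fully decoupled scalar AR models).
#' @param lag_mode `"diagonal"` restricts `D_2..D_d` to diagonals (AR
#'   flavor); `"full"` estimates full matrices (VAR flavor).
#' @param lambda nonnegative LASSO weight on the sum of absolute
#'   coefficients (objective scale: RSS + lambda * sum|coef|).
#' @return object of class `linear_ar_model` with fields `W` (n x n),
#'   `lags` (list over lags 2..d of n x n matrices), `d`, `structure`,
#'   `lag_mode`, `lambda`, `center`, `fit_time`.
#' @export
fit_ar <- function(train, d = 1L, structure = c("dense", "sparse", "scalar"),
                   lag_mode = c("diagonal", "full"), lambda = 0) {
  structure_ <- match.arg(structure)
  lag_mode <- match.arg(lag_mode)
  d <- check_count(d, "d")
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop_invalid("'lambda' must be a single nonnegative number")
  if (structure_ == "sparse" && lambda <= 0)
    stop_invalid("sparse structure requires lambda > 0")
  segments <- as_segments(train)
  assert_clean(segments)
  n <- n_channels(segments[[1L]])
  t0 <- proc.time()[["elapsed"]]

  des <- build_ar_design(segments, d, structure_, lag_mode)
  nrows <- nrow(des$X)
  k_eq <- if (structure_ == "scalar") d
          else n + (d - 1L) * (if (lag_mode == "full") n else 1L)
  if (nrows <= 10L * k_eq)
    stop_samples(sprintf(
      "%d usable training rows for %d free parameters per equation (need > %d)",
      nrows, k_eq, 10L * k_eq))

  W <- matrix(0, n, n)
  lags <- if (d > 1L) replicate(d - 1L, matrix(0, n, n), simplify = FALSE)
          else list()

  for (i in seq_len(n)) {
    # columns of the design available to channel i
    cols <- if (structure_ == "scalar") {
      c(i, if (d > 1L) n * (1:(d - 1L)) + i)
    } else if (lag_mode == "diagonal") {
      c(seq_len(n), if (d > 1L) n * (1:(d - 1L)) + i)
    } else {
      seq_len(n * d)
    }
    Xi <- des$X[, cols, drop = FALSE]
    yi <- des$Y[, i]
    if (lambda == 0) {
      beta <- qr.coef(qr(Xi), yi)
      beta[is.na(beta)] <- 0
    } else if (ncol(Xi) == 1L) {
      # closed-form LASSO for a single predictor: soft-thresholded projection
      xy <- sum(Xi * yi); xx <- sum(Xi^2)
      beta <- sign(xy) * max(abs(xy) - lambda / 2, 0) / xx
    } else {
      fit <- glmnet::glmnet(Xi, yi, alpha = 1,
                            lambda = lambda / (2 * length(yi)),
                            standardize = TRUE, intercept = FALSE)
      beta <- as.numeric(fit$beta)
    }
    if (structure_ == "scalar") {
      W[i, i] <- beta[1L]
      if (d > 1L) for (p in 2:d) lags[[p - 1L]][i, i] <- beta[p]
    } else if (lag_mode == "diagonal") {
      W[i, ] <- beta[seq_len(n)]
      if (d > 1L) for (p in 2:d) lags[[p - 1L]][i, i] <- beta[n + p - 1L]
    } else {
      W[i, ] <- beta[seq_len(n)]
      if (d > 1L) for (p in 2:d)
        lags[[p - 1L]][i, ] <- beta[(p - 1L) * n + seq_len(n)]
    }
  }
  center <- rowMeans(do.call(cbind, lapply(segments, function(s) s$values)))
  structure(list(W = W, lags = lags, d = d, structure = structure_,
                 lag_mode = lag_mode, lambda = lambda, center = center,
                 n = n, labels = segments[[1L]]$labels,
                 fit_time = proc.time()[["elapsed"]] - t0),
            class = "linear_ar_model")
}

#' @export
print.linear_ar_model <- function(x, ...) {
  cat(sprintf("<linear_ar_model> n = %d, d = %d, %s/%s, lambda = %g\n",
              x$n, x$d, x$structure, x$lag_mode, x$lambda))
  invisible(x)
}

#' Predict one step ahead with a fitted linear (V)AR model
#'
#' Emits `yhat(t | t-1) = y(t-1) + W (y(t-1) - mu) + sum_p D_p (y(t-p) - mu)`
#' for `t = d+1, ..., N` of the test segment, where `mu` is the stored
#' training mean.
#'
#' @param model a `linear_ar_model` from [fit_ar].
#' @param test a [recording] or matrix with more than `d` samples.
#' @return a [prediction_set].
#' @export
predict_linear <- function(model, test) {
  stopifnot(inherits(model, "linear_ar_model"))
  test <- as_segments(test)[[1L]]
  assert_clean(list(test))
  if (n_channels(test) != model$n)
    stop_shape(sprintf("model has %d channels, test has %d",
                       model$n, n_channels(test)))
  y <- test$values
  N <- ncol(y)
  d <- model$d
  if (N <= d) stop_samples("test segment shorter than the model order")
  t0 <- proc.time()[["elapsed"]]
  yc <- y - model$center
  tt <- (d + 1L):N
  pred <- y[, tt - 1L, drop = FALSE] + model$W %*% yc[, tt - 1L, drop = FALSE]
  if (d > 1L)
    for (p in 2:d)
      pred <- pred + model$lags[[p - 1L]] %*% yc[, tt - p, drop = FALSE]
  prediction_set(pred, y[, tt, drop = FALSE], indices = tt,
                 family = sprintf("linear-%s-%s-%d", model$structure,
                                  model$lag_mode, d),
                 fit_time = model$fit_time,
                 predict_time = proc.time()[["elapsed"]] - t0)
}
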
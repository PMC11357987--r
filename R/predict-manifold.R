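# Locally linear ("model on demand") predictor: order-1 local polynomial
# regression with Gaussian distance weights. For each query, training points
# are weighted by exp(-||q_m - q_l||^2 / (2 h^2)) and a weighted least
# squares plane [c W] is fit through the tolerance-truncated pseudo-inverse;
# only the local intercept c (the plane's value at the query) is used.
# h -> Inf makes every weight equal and recovers the global linear model.

#' Manifold predictor configuration
#'
#' @param h Gaussian kernel bandwidth (positive); large values make the
#'   model effectively globally linear.
#' @param d number of stacked lags in the query vector (>= 1).
#' @return list of class `manifold_config`.
#' @export
manifold_config <- function(h, d = 1L) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0)
    stop_invalid("'h' must be a single positive number")
  structure(list(h = h, d = check_count(d, "d")), class = "manifold_config")
}

#' Local-linear (order-1 local polynomial) regression
#'
#' The static workhorse shared by the manifold predictor and the
#' dimensionality experiment: for each test row a Gaussian-weighted linear
#' fit around the query returns the local intercept. Multiple bandwidths can
#' be evaluated in one pass (the squared distances are reused).
#'
#' @param X_train,Y_train training predictors (rows = samples) and targets
#'   (vector or matrix with one row per sample).
#' @param X_test test predictors.
#' @param h bandwidth, or vector of bandwidths.
#' @param tol pseudo-inverse truncation tolerance.
#' @return if `Y_train` is a vector and `h` scalar, a vector of predictions;
#'   otherwise an array `[test, target, h]` (dropped dimensions removed).
#' @export
local_linear_regression <- function(X_train, Y_train, X_test, h,
                                    tol = 1e-10) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  Yv <- is.vector(Y_train) || (is.matrix(Y_train) && ncol(Y_train) == 1L)
  Y <- as.matrix(Y_train)
  if (nrow(Y) != nrow(X_train))
    stop_shape("'Y_train' must have one row per training sample")
  if (any(h <= 0)) stop_invalid("'h' must be positive")
  if (nrow(X_train) < ncol(X_train) + 2L)
    stop_samples("need at least dim + 2 training samples for a local plane")
  nte <- nrow(X_test); nh <- length(h); ntg <- ncol(Y)
  out <- array(NA_real_, c(nte, ntg, nh))
  glob <- NULL
  warned <- FALSE
  for (l in seq_len(nte)) {
    dx <- sweep(X_train, 2L, X_test[l, ])
    d2 <- rowSums(dx^2)
    Phi <- cbind(1, dx)
    for (j in seq_len(nh)) {
      w <- exp(-d2 / (2 * h[j]^2))
      if (max(w) < 1e-300) {
        # no training point carries weight: fall back to the global fit
        if (is.null(glob))
          glob <- qr(cbind(1, X_train))
        if (!warned) {
          warning("all local weights are numerically zero; falling back to a global linear fit")
          warned <- TRUE
        }
        cf <- qr.coef(glob, Y); cf[is.na(cf)] <- 0
        out[l, , j] <- c(1, X_test[l, ]) %*% cf
        next
      }
      A <- crossprod(Phi * sqrt(w))
      B <- crossprod(Phi * w, Y)
      out[l, , j] <- pinv_solve(A, B, tol)[1L, ]
    }
  }
  drop(out)
}

#' Locally linear one-step-ahead prediction
#'
#' For each test time the query vector stacks `d` lags of all channels; the
#' predicted first difference is the local intercept of a Gaussian-weighted
#' order-1 polynomial fit over all training queries, and
#' `yhat(t | t-1) = y(t-1) + c`. Model on demand: there is no training
#' phase, so fit time is defined as zero.
#'
#' @param train training [recording], matrix, or list of segments.
#' @param test test [recording] or matrix.
#' @param config a [manifold_config].
#' @return a [prediction_set] for `t = d+1, ..., N`.
#' @export
manifold_predict <- function(train, test, config) {
  stopifnot(inherits(config, "manifold_config"))
  segments <- as_segments(train)
  test <- as_segments(test)[[1L]]
  assert_clean(c(segments, list(test)))
  d <- config$d
  n <- n_channels(test)
  qs <- lag_queries(segments, d)
  if (nrow(qs$X) < n * d + 2L)
    stop_samples("not enough training samples for the stacked-lag local fit")
  y <- test$values
  N <- ncol(y)
  if (N <= d) stop_samples("test segment shorter than the lag depth")
  t0 <- proc.time()[["elapsed"]]
  tq <- lag_queries(list(test), d)
  delta <- local_linear_regression(qs$X, qs$DY, tq$X, config$h)
  delta <- matrix(delta, nrow = nrow(tq$X))
  tt <- (d + 1L):N
  pred <- y[, tt - 1L, drop = FALSE] + t(delta)
  prediction_set(pred, y[, tt, drop = FALSE], indices = tt,
                 family = sprintf("manifold-h%g", config$h),
                 fit_time = 0,
                 predict_time = proc.time()[["elapsed"]] - t0)
}

# Stacked-lag query matrix and first-difference targets for a segment list.
# Rows of X: [y(t-1)' ... y(t-d)'] for t = d+1..N; rows of DY: (y(t)-y(t-1))'.
lag_queries <- function(segments, d) {
  Xs <- list(); Ds <- list()
  for (seg in segments) {
    y <- seg$values
    N <- ncol(y)
    if (N <= d) next
    tt <- (d + 1L):N
    X <- do.call(cbind, lapply(seq_len(d), function(p)
      t(y[, tt - p, drop = FALSE])))
    Xs[[length(Xs) + 1L]] <- X
    Ds[[length(Ds) + 1L]] <- t(y[, tt, drop = FALSE] - y[, tt - 1L, drop = FALSE])
  }
  if (!length(Xs)) stop_samples("no segment is longer than the lag depth")
  list(X = do.call(rbind, Xs), DY = do.call(rbind, Ds))
}
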
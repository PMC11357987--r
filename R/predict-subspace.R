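# Stochastic subspace identification of an innovation-form state-space
# model, with the steady-state one-step predictor obtained from the
# discrete algebraic Riccati recursion.
#
#   x(t+1) = A x(t) + w(t),   y(t) = C x(t) + v(t),
#   Cov([w; v]) = [Q M; M' R]
#
# Projection variant: past and future output block-Hankel matrices (s past
# and r future block rows) are formed from the data, the future is
# projected onto the row space of the past, and the order-n_x truncated SVD
# of the projection yields the observability matrix and a Kalman-like state
# sequence. (A, C) and the noise covariance triplet (Q, M, R) come from
# least-squares regressions on that state sequence; since (Q, M, R) is a
# genuine sample covariance (positive semidefinite by construction), the
# filter Riccati recursion for the steady-state predictor gain is
# well-posed. The predictor form is x(t+1) = A x + K e, y = C x + e.

#' Fit a stochastic subspace state-space model
#'
#' @param train a [recording], matrix, or list of segments (the first
#'   segment's channel count sets the output dimension; segments are used
#'   jointly for covariance estimation).
#' @param n_x state dimension (>= 1, at most `r * n`).
#' @param r number of future block rows in the covariance Hankel matrix.
#' @param s number of past block columns.
#' @return object of class `subspace_model` with fields `A`, `C`, `K`
#'   (predictor gain), `Q`, `M`, `R` (innovation-consistent noise
#'   covariances), `sigma_e` (innovation covariance), `center`, `r`, `s`,
#'   `n_x`, `singular_values`.
#' @export
fit_subspace <- function(train, n_x, r = max(2L, n_x), s = r) {
  n_x <- check_count(n_x, "n_x")
  r <- check_count(r, "r", min = 2L); s <- check_count(s, "s")
  segments <- as_segments(train)
  assert_clean(segments)
  n <- n_channels(segments[[1L]])
  if (n_x > r * n)
    stop_invalid(sprintf("n_x = %d exceeds r*n = %d", n_x, r * n))
  Ntot <- sum(vapply(segments, n_samples, integer(1)))
  if (Ntot < 10L * (r + s))
    stop_samples(sprintf("training length %d < 10*(r+s) = %d", Ntot, 10L * (r + s)))
  t0 <- proc.time()[["elapsed"]]

  center <- rowMeans(do.call(cbind, lapply(segments, function(x) x$values)))
  # data block-Hankel matrices: past stacks y(t-1)..y(t-s), future stacks
  # y(t)..y(t+r-1); columns pooled over segments
  Yp <- list(); Yf <- list(); Ynow <- list(); Ynext <- list()
  for (seg in segments) {
    yc <- seg$values - center
    N <- ncol(yc)
    ts <- (s + 1L):(N - r)          # need one extra future sample for the shift
    if (length(ts) < 2L) next
    Yp[[length(Yp) + 1L]] <- do.call(rbind, lapply(seq_len(s), function(p)
      yc[, ts - p, drop = FALSE]))
    Yf[[length(Yf) + 1L]] <- do.call(rbind, lapply(seq_len(r) - 1L, function(p)
      yc[, ts + p, drop = FALSE]))
    Ynow[[length(Ynow) + 1L]] <- yc[, ts, drop = FALSE]
  }
  if (!length(Yp))
    stop_samples("no training segment is long enough for the chosen r and s")
  Yp <- do.call(cbind, Yp); Yf <- do.call(cbind, Yf)
  Ynow <- do.call(cbind, Ynow)
  j <- ncol(Yp)
  # orthogonal projection of the future row space onto the past row space
  Theta <- tcrossprod(Yf, Yp) %*% pinv(tcrossprod(Yp, Yp))
  Oproj <- Theta %*% Yp
  sv <- svd(Oproj, nu = n_x, nv = n_x)
  rank_num <- sum(sv$d > 1e-10 * sv$d[1L])
  if (n_x > rank_num)
    warning(sprintf("requested n_x = %d exceeds the numerical rank %d of the subspace projection",
                    n_x, rank_num))
  sq <- sqrt(sv$d[seq_len(n_x)])
  X <- t(sv$v) * sq                     # Kalman-like state sequence, n_x x j
  # system matrices by least squares on the state sequence
  X0 <- X[, -j, drop = FALSE]; X1 <- X[, -1L, drop = FALSE]
  A <- t(pinv_solve(tcrossprod(X0, X0), tcrossprod(X0, X1)))
  C <- t(pinv_solve(tcrossprod(X0, X0), tcrossprod(X0, Ynow[, -j, drop = FALSE])))
  W <- X1 - A %*% X0
  V <- Ynow[, -j, drop = FALSE] - C %*% X0
  Q <- tcrossprod(W, W) / (j - 1L)
  Rm <- tcrossprod(V, V) / (j - 1L)
  M <- tcrossprod(W, V) / (j - 1L)

  # filter Riccati recursion for the steady-state predictor gain
  P <- Q
  converged <- FALSE
  for (it in seq_len(10000L)) {
    S <- C %*% P %*% t(C) + Rm
    Kt <- (A %*% P %*% t(C) + M) %*% pinv(S)
    Pn <- A %*% P %*% t(A) + Q - Kt %*% t(A %*% P %*% t(C) + M)
    if (max(abs(Pn - P)) < 1e-10) { P <- Pn; converged <- TRUE; break }
    P <- Pn
  }
  if (!converged)
    stop_numeric("Riccati recursion did not converge in 10000 iterations")
  sigma_e <- C %*% P %*% t(C) + Rm
  K <- (A %*% P %*% t(C) + M) %*% pinv(sigma_e)
  structure(list(A = A, C = C, K = K, Q = Q, M = M, R = Rm,
                 sigma_e = sigma_e, center = center, r = r, s = s,
                 n_x = n_x, n = n, singular_values = sv$d,
                 fit_time = proc.time()[["elapsed"]] - t0),
            class = "subspace_model")
}

#' @export
print.subspace_model <- function(x, ...) {
  cat(sprintf("<subspace_model> n = %d, n_x = %d, r = %d, s = %d, predictor radius %.3f\n",
              x$n, x$n_x, x$r, x$s,
              spectral_radius(x$A - x$K %*% x$C)))
  invisible(x)
}

#' One-step prediction with a fitted subspace model
#'
#' Runs the steady-state predictor filter
#' `xhat(t+1) = (A - K C) xhat(t) + K (y(t) - mu)`,
#' `yhat(t | t-1) = C xhat(t) + mu` from a zero initial state. The first
#' `max(r, s)` predictions are flagged as filter burn-in and excluded from
#' scoring by default.
#'
#' @param model a `subspace_model`.
#' @param test a [recording] or matrix with at least 2 samples.
#' @return a [prediction_set].
#' @export
predict_subspace <- function(model, test) {
  stopifnot(inherits(model, "subspace_model"))
  test <- as_segments(test)[[1L]]
  assert_clean(list(test))
  if (n_channels(test) != model$n)
    stop_shape("channel count mismatch between model and test recording")
  rad <- spectral_radius(model$A - model$K %*% model$C)
  if (rad >= 1)
    stop_numeric(sprintf("unstable predictor (spectral radius %.4f >= 1); refusing to filter", rad))
  y <- test$values
  N <- ncol(y)
  if (N < 2L) stop_samples("test segment needs at least 2 samples")
  t0 <- proc.time()[["elapsed"]]
  yc <- y - model$center
  x <- matrix(0, model$n_x, 1L)
  pred <- matrix(NA_real_, model$n, N)
  for (t in seq_len(N)) {
    pred[, t] <- model$C %*% x + model$center
    x <- model$A %*% x + model$K %*% (yc[, t, drop = FALSE] - model$C %*% x)
  }
  tt <- 2:N
  burn <- tt[tt <= min(max(model$r, model$s) + 1L, N)]
  prediction_set(pred[, tt, drop = FALSE], y[, tt, drop = FALSE],
                 indices = tt, family = sprintf("subspace-%d", model$n_x),
                 fit_time = model$fit_time,
                 predict_time = proc.time()[["elapsed"]] - t0,
                 burn_in = burn)
}
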
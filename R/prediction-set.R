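#' One-step-ahead prediction set
#'
#' Aligned container produced by every predictor: predictions
#' `yhat(t | t-1)` for a set of test indices, the matching actual samples,
#' and the residuals `eps(t) = y(t) - yhat(t | t-1)`. Residuals always equal
#' actual minus predictions elementwise on the index list.
#'
#' @param predictions n x m matrix of one-step predictions.
#' @param actual n x m matrix of the corresponding observed samples.
#' @param indices integer vector (length m) of time indices within the test
#'   segment the columns refer to.
#' @param family character tag of the producing model family.
#' @param fit_time,predict_time wall-clock seconds (training time is defined
#'   as zero for model-on-demand predictors).
#' @param burn_in indices (subset of `indices`) flagged as predictor burn-in
#'   and excluded from scoring by default.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(predictions, actual, indices, family = "unknown",
                           fit_time = 0, predict_time = 0,
                           burn_in = integer(0)) {
  predictions <- as.matrix(predictions)
  actual <- as.matrix(actual)
  if (!all(dim(predictions) == dim(actual)))
    stop_shape("'predictions' and 'actual' must have identical shapes")
  if (length(indices) != ncol(predictions))
    stop_shape("'indices' must have one entry per predicted column")
  structure(list(predictions = predictions,
                 actual = actual,
                 residuals = actual - predictions,
                 indices = as.integer(indices),
                 family = family,
                 fit_time = fit_time,
                 predict_time = predict_time,
                 burn_in = as.integer(burn_in)),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set '%s'> %d channel(s), %d predicted sample(s)\n",
              x$family, nrow(x$predictions), ncol(x$predictions)))
  invisible(x)
}

# Columns retained for scoring (burn-in removed).
scored_columns <- function(ps) {
  if (length(ps$burn_in)) which(!(ps$indices %in% ps$burn_in))
  else seq_along(ps$indices)
}

#' Zero-order-hold (random-walk) baseline predictor
#'
#' The naive baseline `yhat(t | t-1) = y(t-1)`; every candidate model must
#' beat it to claim any captured dynamics beyond a random walk.
#'
#' @param test a [recording] (or matrix) with at least 2 samples.
#' @return a [prediction_set] for `t = 2, ..., N`.
#' @examples
#' ps <- predict_zero(recording(matrix(c(3, 5, 4), 1)))
#' ps$predictions  # 3, 5
#' ps$residuals    # 2, -1
#' @export
predict_zero <- function(test) {
  test <- as_segments(test)[[1L]]
  assert_clean(list(test))
  y <- test$values
  N <- ncol(y)
  if (N < 2L) stop_samples("the zero model needs at least 2 samples")
  t0 <- proc.time()[["elapsed"]]
  ps <- prediction_set(y[, -N, drop = FALSE], y[, -1L, drop = FALSE],
                       indices = 2:N, family = "zero",
                       fit_time = 0,
                       predict_time = proc.time()[["elapsed"]] - t0)
  ps
}
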
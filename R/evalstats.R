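# Scoring (per-channel prediction R^2, residual whiteness), cross-validation
# plans, and paired statistical comparison of model families.

#' Per-channel prediction R-squared
#'
#' `R2_i = 1 - sum_t eps_i(t)^2 / sum_t (y_i(t) - ybar_i)^2`, where `ybar_i`
#' is the mean of the scored test samples, so `R2 = 0` means exactly "as
#' good as the constant predictor" on the scored segment. `R2 <= 1` always
#' and can be negative. Channels with a constant test signal get an `NA`
#' sentinel (undefined R-squared) and are excluded from summary medians.
#'
#' @param actual,predicted n x m matrices (or vectors) of observed and
#'   predicted samples, column-aligned.
#' @param baseline optional n-vector to use as `ybar` instead of the scored
#'   test mean.
#' @return object of class `channel_r2`: `r2` (n-vector), `baseline_mean`,
#'   `n_samples`.
#' @examples
#' r2_per_channel(c(1, 2, 3), c(3, 3, 3))$r2  # -1.5
#' @export
r2_per_channel <- function(actual, predicted, baseline = NULL) {
  if (is.vector(actual)) actual <- matrix(actual, nrow = 1L)
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1L)
  if (!all(dim(actual) == dim(predicted)))
    stop_shape("'actual' and 'predicted' must have identical shapes")
  if (ncol(actual) < 2L) stop_samples("need at least 2 scored samples")
  ybar <- if (is.null(baseline)) rowMeans(actual) else baseline
  sse <- rowSums((actual - predicted)^2)
  sst <- rowSums((actual - ybar)^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
  structure(list(r2 = r2, baseline_mean = ybar, n_samples = ncol(actual)),
            class = "channel_r2")
}

#' R-squared of a prediction set
#'
#' Convenience wrapper applying [r2_per_channel] to a [prediction_set],
#' excluding burn-in columns.
#'
#' @param ps a [prediction_set].
#' @return a `channel_r2`.
#' @export
r2_score <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  cols <- scored_columns(ps)
  if (length(cols) < 2L) stop_samples("too few scored samples after burn-in removal")
  r2_per_channel(ps$actual[, cols, drop = FALSE],
                 ps$predictions[, cols, drop = FALSE])
}

#' Multivariate portmanteau whiteness statistic
#'
#' `Q = (N - M) * sum_{i=1..M} tr( R(i)' R(0)^+ R(i) R(0)^+ )` with
#' `R(i) = 1/(N-M) * sum_{t=0}^{N-M-1} e(t+i) e(t)'` and `^+` the
#' tolerance-truncated pseudo-inverse (truncation at 1e-10 of the largest
#' singular value). Large `Q` indicates residual autocorrelation, i.e. that
#' temporal structure remains unmodelled.
#'
#' @param residuals n x N matrix (or vector) of residuals.
#' @param M number of cross-correlation lags (1 <= M < N).
#' @return the scalar Q statistic.
#' @export
portmanteau_q <- function(residuals, M) {
  if (is.vector(residuals)) residuals <- matrix(residuals, nrow = 1L)
  N <- ncol(residuals)
  M <- check_count(M, "M")
  if (M >= N) stop_invalid("'M' must be smaller than the residual length")
  base <- residuals[, 1:(N - M), drop = FALSE]
  R0 <- tcrossprod(base, base) / (N - M)
  R0i <- pinv(R0)
  q <- 0
  for (i in seq_len(M)) {
    Ri <- tcrossprod(residuals[, (1 + i):(N - M + i), drop = FALSE], base) /
      (N - M)
    q <- q + sum(diag(t(Ri) %*% R0i %*% Ri %*% R0i))
  }
  (N - M) * q
}

#' Randomization test of residual whiteness
#'
#' The null distribution of [portmanteau_q] is generated by shuffling the
#' time indices of the residuals `n_shuffles` times; the rejection threshold
#' `Q_thr` is the 95th percentile of the shuffled statistics. A ratio
#' `Q / Q_thr <= 1` means the null hypothesis of whiteness is not rejected.
#'
#' @param residuals n x N matrix (or vector) of residuals.
#' @param M lag count; default `min(20, floor(N/5))`.
#' @param n_shuffles number of random time permutations (default 100).
#' @param seed integer seed making the threshold reproducible.
#' @return object of class `whiteness_result`: `Q`, `Q_thr`, `ratio`, `M`,
#'   `n_shuffles`, `seed`.
#' @export
whiteness_test <- function(residuals, M = NULL, n_shuffles = 100L, seed = 1L) {
  if (is.vector(residuals)) residuals <- matrix(residuals, nrow = 1L)
  N <- ncol(residuals)
  if (is.null(M)) M <- max(1L, min(20L, floor(N / 5)))
  n_shuffles <- check_count(n_shuffles, "n_shuffles")
  if (n_shuffles < 20L)
    warning("fewer than 20 shuffles makes the 95th-percentile threshold unstable")
  Q <- portmanteau_q(residuals, M)
  qs <- local_seed(seed, vapply(seq_len(n_shuffles), function(b) {
    portmanteau_q(residuals[, sample.int(N), drop = FALSE], M)
  }, numeric(1)))
  Q_thr <- as.numeric(quantile(qs, 0.95))
  structure(list(Q = Q, Q_thr = Q_thr, ratio = Q / Q_thr, M = M,
                 n_shuffles = n_shuffles, seed = seed),
            class = "whiteness_result")
}

#' @export
print.whiteness_result <- function(x, ...) {
  cat(sprintf("<whiteness_result> Q = %.3f, Q_thr = %.3f, Q/Q_thr = %.3f (M = %d)%s\n",
              x$Q, x$Q_thr, x$ratio, x$M,
              if (x$ratio <= 1) " [whiteness not rejected]" else " [rejected]"))
  invisible(x)
}

#' Chi-squared whiteness test for a univariate residual series
#'
#' Box–Pierce statistic `N * sum_{i=1..M} rho(i)^2` referred to a
#' chi-squared distribution with `M` degrees of freedom; the Ljung–Box
#' small-sample correction is available via `type`.
#'
#' @param residual numeric vector.
#' @param M number of autocorrelation lags (`M = 0` returns statistic 0 and
#'   p-value 1).
#' @param type `"box-pierce"` (default) or `"ljung-box"`.
#' @return list with `statistic`, `p_value`, `M`, `type`.
#' @export
chi2_whiteness_univariate <- function(residual, M,
                                      type = c("box-pierce", "ljung-box")) {
  type <- match.arg(type)
  residual <- as.numeric(residual)
  N <- length(residual)
  if (M == 0) return(list(statistic = 0, p_value = 1, M = 0L, type = type))
  M <- check_count(M, "M")
  if (M >= N) stop_invalid("'M' must be smaller than the series length")
  if (var(residual) == 0)
    stop_degenerate("constant residual: autocorrelation undefined")
  rho <- as.numeric(acf(residual, lag.max = M, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  stat <- if (type == "box-pierce") N * sum(rho^2)
          else N * (N + 2) * sum(rho^2 / (N - seq_len(M)))
  list(statistic = stat, p_value = pchisq(stat, df = M, lower.tail = FALSE),
       M = M, type = type)
}

#' Build a cross-validation plan
#'
#' `"fmri"`: each recording is split into two halves; all halves across
#' recordings become segments and the plan is leave-one-segment-out (4
#' recordings of 1200 samples give 8 folds with 600-sample test segments).
#' With `reduce = "second_quarter"` only the second quarter of each segment
#' is used (600-sample segments become 150), mirroring the reduced plan used
#' for computationally heavy pairwise predictors. `"ieeg"`: each recording
#' is a single fold with the leading `train_fraction` (default 0.8, i.e.
#' the first 8 s of a 10 s segment) for training and the trailing remainder
#' for testing. `"custom"`: leave-one-segment-out over the recordings as
#' given.
#'
#' @param recordings a [recording] or list of recordings.
#' @param modality `"fmri"`, `"ieeg"`, or `"custom"`.
#' @param train_fraction leading fraction used for training in iEEG-like
#'   plans.
#' @param reduce `"none"` or `"second_quarter"` (fMRI-like plans only).
#' @return object of class `cv_plan`: `segments` (list of recordings) and
#'   `folds` (list of `list(train = indices, test = index)`), plus the
#'   modality tag.
#' @export
build_cv_plan <- function(recordings, modality = c("fmri", "ieeg", "custom"),
                          train_fraction = 0.8,
                          reduce = c("none", "second_quarter")) {
  modality <- match.arg(modality)
  reduce <- match.arg(reduce)
  recs <- as_segments(recordings)
  if (modality == "fmri") {
    segments <- list()
    for (r in recs) {
      N <- n_samples(r)
      if (N < 4L) stop_samples("recording too short to split into halves")
      half <- N %/% 2L
      pieces <- list(r$values[, seq_len(half), drop = FALSE],
                     r$values[, half + seq_len(half), drop = FALSE])
      if (reduce == "second_quarter")
        pieces <- lapply(pieces, function(m) {
          L <- ncol(m); q <- L %/% 4L
          if (q < 2L) stop_samples("segment too short for quarter reduction")
          m[, q + seq_len(q), drop = FALSE]
        })
      for (p in pieces)
        segments[[length(segments) + 1L]] <-
          recording(p, sampling_interval = r$sampling_interval,
                    labels = r$labels)
    }
    k <- length(segments)
    folds <- lapply(seq_len(k), function(i)
      list(train = setdiff(seq_len(k), i), test = i))
  } else if (modality == "ieeg") {
    segments <- list(); folds <- list()
    for (r in recs) {
      N <- n_samples(r)
      n_tr <- floor(train_fraction * N)
      if (n_tr < 2L || N - n_tr < 2L)
        stop_samples("recording too short for the train/test split")
      segments[[length(segments) + 1L]] <-
        recording(r$values[, seq_len(n_tr), drop = FALSE],
                  r$sampling_interval, r$labels)
      segments[[length(segments) + 1L]] <-
        recording(r$values[, n_tr + seq_len(N - n_tr), drop = FALSE],
                  r$sampling_interval, r$labels)
      m <- length(segments)
      folds[[length(folds) + 1L]] <- list(train = m - 1L, test = m)
    }
  } else {
    segments <- recs
    k <- length(segments)
    if (k < 2L) stop_samples("custom plans need at least 2 segments")
    folds <- lapply(seq_len(k), function(i)
      list(train = setdiff(seq_len(k), i), test = i))
  }
  structure(list(segments = segments, folds = folds, modality = modality),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan '%s'> %d segment(s), %d fold(s)\n",
              x$modality, length(x$segments), length(x$folds)))
  invisible(x)
}

#' Paired one-sided signed-rank comparison of model families
#'
#' For every ordered pair of rows in the score table a one-sided Wilcoxon
#' signed-rank test (`row > column`) is computed on the paired samples
#' (exact for small zero-free samples, normal approximation with tie
#' correction otherwise; zero differences are discarded). All off-diagonal
#' p-values are corrected by the Benjamini–Hochberg step-up rule at level
#' `alpha`.
#'
#' @param scores methods x samples numeric matrix of paired scores (e.g.
#'   per-channel R-squared), with rownames naming the methods.
#' @param alpha FDR level for the significance mask.
#' @return object of class `comparison_result`: `p` (one-sided p-value
#'   matrix), `significant` (BH mask at `alpha`), `direction` (sign of the
#'   median paired difference), `alpha`.
#' @export
signed_rank_compare <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  k <- nrow(scores)
  if (ncol(scores) < 5L) stop_samples("need at least 5 paired samples")
  if (is.null(rownames(scores))) rownames(scores) <- sprintf("m%d", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(rownames(scores), rownames(scores)))
  direction <- p
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    dif <- scores[a, ] - scores[b, ]
    direction[a, b] <- sign(median(dif))
    if (all(dif == 0)) {
      p[a, b] <- 1  # no information: conventionally non-significant
      next
    }
    p[a, b] <- suppressWarnings(
      wilcox.test(scores[a, ], scores[b, ], paired = TRUE,
                  alternative = "greater")$p.value)
  }
  off <- !is.na(p)
  padj <- p
  padj[off] <- p.adjust(p[off], method = "BH")
  structure(list(p = p, significant = padj <= alpha, direction = direction,
                 p_adjusted = padj, alpha = alpha),
            class = "comparison_result")
}

#' Evaluate one model family over a cross-validation plan
#'
#' Fits the family on each fold's training segments, predicts the test
#' segment, and reports per-fold, per-channel R-squared together with the
#' fold's whiteness statistics and wall times. Training time is defined as
#' zero for the model-on-demand families (`zero`, `manifold`, `mmse`).
#'
#' @param family one of `"zero"`, `"linear"`, `"subspace"`, `"manifold"`,
#'   `"mmse"`, `"mlp"`.
#' @param plan a [build_cv_plan] object.
#' @param ... hyperparameters passed to the family's fit/config function
#'   ([fit_ar], [fit_subspace], [manifold_config], [mmse_config],
#'   [mlp_config]).
#' @param whiteness_lags lag count for the whiteness test (`NULL` for the
#'   default rule).
#' @param seed integer root seed (whiteness shuffles, MLP training).
#' @return data frame with columns `family`, `fold`, `channel`, `r2`, `Q`,
#'   `Q_thr`, `ratio`, `fit_time`, `predict_time`, `seed`.
#' @export
evaluate_model <- function(family = c("zero", "linear", "subspace",
                                      "manifold", "mmse", "mlp"),
                           plan, ..., whiteness_lags = NULL, seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(plan, "cv_plan"))
  dots <- list(...)
  rows <- list()
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    train <- plan$segments[fold$train]
    test <- plan$segments[[fold$test]]
    ps <- switch(family,
      zero = predict_zero(test),
      linear = {
        model <- do.call(fit_ar, c(list(train), dots))
        predict_linear(model, test)
      },
      subspace = {
        model <- do.call(fit_subspace, c(list(train), dots))
        predict_subspace(model, test)
      },
      manifold = manifold_predict(train, test, do.call(manifold_config, dots)),
      mmse = mmse_predict(train, test, do.call(mmse_config, dots)),
      mlp = {
        model <- do.call(fit_mlp, c(list(train),
                                    if (length(dots)) list(config = do.call(mlp_config, dots)),
                                    list(seed = seed)))
        predict_mlp(model, test)
      })
    sc <- r2_score(ps)
    cols <- scored_columns(ps)
    wt <- whiteness_test(ps$residuals[, cols, drop = FALSE],
                         M = whiteness_lags, seed = seed + f)
    labels <- test$labels
    rows[[f]] <- data.frame(
      family = family, fold = f, channel = labels,
      r2 = unname(sc$r2), Q = wt$Q, Q_thr = wt$Q_thr, ratio = wt$ratio,
      fit_time = ps$fit_time, predict_time = ps$predict_time,
      seed = seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
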
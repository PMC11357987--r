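# A small fully connected NARX network mapping stacked lags
# (y(t-1), ..., y(t-d)) to the first difference y(t) - y(t-1).
# Architecture: input -> D x [fully connected -> batch norm -> ReLU ->
# dropout 0.5] -> fully connected -> output. Trained with minibatch Adam,
# fixed seed, early stopping on a validation split; evaluation runs with
# dropout off and batch-norm running statistics.

#' MLP predictor configuration
#'
#' @param depth number of hidden blocks (>= 1).
#' @param width units per hidden block (>= 1).
#' @param d number of stacked input lags.
#' @param dropout dropout probability applied after each hidden block
#'   during training (default 0.5).
#' @param batchnorm logical: apply batch normalization before each ReLU.
#' @param activation `"relu"` or `"identity"` (the latter makes the whole
#'   network an affine map and is useful as a linear control).
#' @param epochs training epoch cap.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction fraction of training rows held out for early
#'   stopping.
#' @param patience epochs without validation improvement before stopping.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(depth = 1L, width = 10L, d = 1L, dropout = 0.5,
                       batchnorm = TRUE,
                       activation = c("relu", "identity"),
                       epochs = 200L, batch_size = 32L,
                       learning_rate = 1e-2, val_fraction = 0.1,
                       patience = 20L) {
  structure(list(depth = check_count(depth, "depth"),
                 width = check_count(width, "width"),
                 d = check_count(d, "d"),
                 dropout = dropout, batchnorm = isTRUE(batchnorm),
                 activation = match.arg(activation),
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 patience = check_count(patience, "patience")),
            class = "mlp_config")
}

mlp_init <- function(n_in, n_out, cfg) {
  sizes <- c(n_in, rep(cfg$width, cfg$depth))
  layers <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    layers[[k]] <- list(
      W = matrix(rnorm(sizes[k] * cfg$width, sd = sqrt(2 / sizes[k])),
                 sizes[k], cfg$width),
      b = rep(0, cfg$width),
      gamma = rep(1, cfg$width), beta = rep(0, cfg$width),
      run_mean = rep(0, cfg$width), run_var = rep(1, cfg$width))
  }
  list(layers = layers,
       W_out = matrix(rnorm(cfg$width * n_out, sd = sqrt(2 / cfg$width)),
                      cfg$width, n_out),
       b_out = rep(0, n_out))
}

mlp_forward <- function(params, X, cfg, training = FALSE, dropmask = NULL) {
  cache <- list()
  H <- X
  eps <- 1e-5
  for (k in seq_along(params$layers)) {
    ly <- params$layers[[k]]
    Z <- sweep(H %*% ly$W, 2L, ly$b, "+")
    if (cfg$batchnorm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2L, mu)^2)
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      Zh <- sweep(sweep(Z, 2L, mu), 2L, sqrt(v + eps), "/")
      A <- sweep(sweep(Zh, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    } else {
      mu <- NULL; v <- NULL; Zh <- Z; A <- Z
    }
    R <- if (cfg$activation == "relu") pmax(A, 0) else A
    if (training && cfg$dropout > 0) {
      M <- dropmask[[k]]
      R <- R * M / (1 - cfg$dropout)
    }
    cache[[k]] <- list(H_in = H, Z = Z, Zh = Zh, A = A, mu = mu, v = v, R = R)
    H <- R
  }
  out <- sweep(H %*% params$W_out, 2L, params$b_out, "+")
  list(out = out, cache = cache, H_last = H)
}

# Backward pass: returns gradients with the same structure as params.
mlp_backward <- function(params, fw, X, dOut, cfg, dropmask) {
  eps <- 1e-5
  g <- list(layers = vector("list", length(params$layers)))
  g$W_out <- crossprod(fw$H_last, dOut)
  g$b_out <- colSums(dOut)
  dH <- tcrossprod(dOut, params$W_out)
  for (k in rev(seq_along(params$layers))) {
    ca <- fw$cache[[k]]
    ly <- params$layers[[k]]
    dR <- dH
    if (cfg$dropout > 0)
      dR <- dR * dropmask[[k]] / (1 - cfg$dropout)
    dA <- if (cfg$activation == "relu") dR * (ca$A > 0) else dR
    if (cfg$batchnorm) {
      m <- nrow(dA)
      dgamma <- colSums(dA * ca$Zh)
      dbeta <- colSums(dA)
      dZh <- sweep(dA, 2L, ly$gamma, "*")
      iv <- 1 / sqrt(ca$v + eps)
      # standard batch-norm backprop
      dZ <- sweep(dZh, 2L, iv, "*") -
        sweep(matrix(colMeans(dZh), m, ncol(dZh), byrow = TRUE), 2L, iv, "*") -
        sweep(ca$Zh * matrix(colMeans(dZh * ca$Zh), m, ncol(dZh), byrow = TRUE),
              2L, iv, "*")
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZ <- dA
    }
    g$layers[[k]] <- list(W = crossprod(ca$H_in, dZ), b = colSums(dZ),
                          gamma = dgamma, beta = dbeta)
    dH <- tcrossprod(dZ, ly$W)
  }
  g
}

# Flatten/unflatten parameter lists for the Adam update.
mlp_param_names <- function(params, cfg) {
  nm <- list()
  for (k in seq_along(params$layers)) {
    nm[[length(nm) + 1L]] <- c(k, "W"); nm[[length(nm) + 1L]] <- c(k, "b")
    if (cfg$batchnorm) {
      nm[[length(nm) + 1L]] <- c(k, "gamma")
      nm[[length(nm) + 1L]] <- c(k, "beta")
    }
  }
  nm
}

#' Fit an MLP NARX model
#'
#' Trains the network on stacked lags to predict first differences with
#' minibatch Adam under a fixed seed. Inputs are standardized internally
#' (statistics stored on the model). A `val_fraction` tail of the shuffled
#' rows is held out; training stops early when validation loss has not
#' improved for `patience` epochs and the best-validation parameters are
#' kept.
#'
#' @param train training [recording], matrix, or list of segments.
#' @param config an [mlp_config].
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return object of class `mlp_model`.
#' @export
fit_mlp <- function(train, config = mlp_config(), seed = 1L) {
  stopifnot(inherits(config, "mlp_config"))
  segments <- as_segments(train)
  assert_clean(segments)
  n <- n_channels(segments[[1L]])
  qs <- lag_queries(segments, config$d)
  X <- qs$X; Y <- qs$DY
  if (nrow(X) <= config$batch_size)
    stop_samples("need more training rows than the batch size")
  x_mu <- colMeans(X); x_sd <- apply(X, 2L, sd)
  x_sd[x_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2L, x_mu), 2L, x_sd, "/")
  t0 <- proc.time()[["elapsed"]]
  params <- local_seed(seed, {
    params <- mlp_init(ncol(Xs), n, config)
    nrows <- nrow(Xs)
    perm <- sample.int(nrows)
    n_val <- max(1L, floor(config$val_fraction * nrows))
    val <- perm[seq_len(n_val)]
    tr <- perm[-seq_len(n_val)]
    m1 <- rapply(params, function(x) x * 0, how = "replace")
    m2 <- m1
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; step <- 0L
    best <- list(loss = Inf, params = params, wait = 0L)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        if (length(rows) < 2L) next
        Xb <- Xs[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        dropmask <- if (config$dropout > 0)
          lapply(seq_len(config$depth), function(k)
            matrix(runif(length(rows) * config$width) >= config$dropout,
                   length(rows), config$width))
        else NULL
        fw <- mlp_forward(params, Xb, config, training = TRUE,
                          dropmask = dropmask)
        err <- fw$out - Yb
        if (!all(is.finite(err)))
          pem_stop("non-finite training loss", "pembench_training_failure")
        dOut <- 2 * err / length(err)
        gr <- mlp_backward(params, fw, Xb, dOut, config, dropmask)
        # update batch-norm running statistics
        if (config$batchnorm)
          for (k in seq_len(config$depth)) {
            ca <- fw$cache[[k]]
            params$layers[[k]]$run_mean <-
              0.9 * params$layers[[k]]$run_mean + 0.1 * ca$mu
            params$layers[[k]]$run_var <-
              0.9 * params$layers[[k]]$run_var + 0.1 * ca$v
          }
        step <- step + 1L
        upd <- function(p, g, m1v, m2v) {
          m1v <- b1 * m1v + (1 - b1) * g
          m2v <- b2 * m2v + (1 - b2) * g^2
          mh <- m1v / (1 - b1^step)
          vh <- m2v / (1 - b2^step)
          list(p = p - config$learning_rate * mh / (sqrt(vh) + adam_eps),
               m1 = m1v, m2 = m2v)
        }
        for (nmk in mlp_param_names(params, config)) {
          k <- as.integer(nmk[1L]); f <- nmk[2L]
          u <- upd(params$layers[[k]][[f]], gr$layers[[k]][[f]],
                   m1$layers[[k]][[f]], m2$layers[[k]][[f]])
          params$layers[[k]][[f]] <- u$p
          m1$layers[[k]][[f]] <- u$m1; m2$layers[[k]][[f]] <- u$m2
        }
        u <- upd(params$W_out, gr$W_out, m1$W_out, m2$W_out)
        params$W_out <- u$p; m1$W_out <- u$m1; m2$W_out <- u$m2
        u <- upd(params$b_out, gr$b_out, m1$b_out, m2$b_out)
        params$b_out <- u$p; m1$b_out <- u$m1; m2$b_out <- u$m2
      }
      vloss <- mean((mlp_forward(params, Xs[val, , drop = FALSE], config,
                                 training = FALSE)$out -
                       Y[val, , drop = FALSE])^2)
      if (vloss < best$loss - 1e-12) {
        best <- list(loss = vloss, params = params, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= config$patience) break
      }
    }
    best$params
  })
  structure(list(params = params, config = config, n = n,
                 x_mu = x_mu, x_sd = x_sd, seed = seed,
                 fit_time = proc.time()[["elapsed"]] - t0),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d block(s) x %d units, d = %d, activation %s\n",
              x$config$depth, x$config$width, x$config$d,
              x$config$activation))
  invisible(x)
}

#' Predict one step ahead with a fitted MLP NARX model
#'
#' Runs the network in evaluation mode (dropout disabled, batch-norm using
#' running statistics): `yhat(t | t-1) = y(t-1) + f(lags)`.
#'
#' @param model an `mlp_model` from [fit_mlp].
#' @param test a [recording] or matrix.
#' @return a [prediction_set] for `t = d+1, ..., N`.
#' @export
predict_mlp <- function(model, test) {
  stopifnot(inherits(model, "mlp_model"))
  test <- as_segments(test)[[1L]]
  assert_clean(list(test))
  if (n_channels(test) != model$n)
    stop_shape("channel count mismatch between model and test recording")
  d <- model$config$d
  y <- test$values
  N <- ncol(y)
  if (N <= d) stop_samples("test segment shorter than the lag depth")
  t0 <- proc.time()[["elapsed"]]
  tq <- lag_queries(list(test), d)
  Xs <- sweep(sweep(tq$X, 2L, model$x_mu), 2L, model$x_sd, "/")
  delta <- mlp_forward(model$params, Xs, model$config, training = FALSE)$out
  tt <- (d + 1L):N
  pred <- y[, tt - 1L, drop = FALSE] + t(delta)
  prediction_set(pred, y[, tt, drop = FALSE], indices = tt,
                 family = "mlp",
                 fit_time = model$fit_time,
                 predict_time = proc.time()[["elapsed"]] - t0)
}
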
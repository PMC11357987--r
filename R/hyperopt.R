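# Stochastic hyperparameter search over hypercubic meshes or coordinate
# directions with minibatch objective evaluation. Integer parameters jump
# to the best candidate; real parameters take a finite-difference
# gradient-ascent step.

#' Hyperparameter definition
#'
#' @param name parameter name.
#' @param kind `"integer"` or `"real"`.
#' @param init initial value (within bounds).
#' @param lower,upper bounds.
#' @param step probe step for candidate generation: defaults to 1 for
#'   integers and 1e-6 for reals.
#' @return list of class `hyperparam`.
#' @export
hyperparam <- function(name, kind = c("integer", "real"), init, lower, upper,
                       step = NULL) {
  kind <- match.arg(kind)
  if (is.null(step)) step <- if (kind == "integer") 1 else 1e-6
  if (step <= 0) stop_invalid("'step' must be positive")
  if (init < lower || init > upper)
    stop_invalid(sprintf("initial value of '%s' outside its bounds", name))
  structure(list(name = name, kind = kind, init = init,
                 lower = lower, upper = upper, step = step),
            class = "hyperparam")
}

clip_state <- function(state, defs) {
  for (k in seq_along(defs)) {
    state[k] <- min(max(state[k], defs[[k]]$lower), defs[[k]]$upper)
    if (defs[[k]]$kind == "integer") state[k] <- round(state[k])
  }
  state
}

#' Hypercubic mesh of candidate hyperparameter vectors
#'
#' All `3^N` combinations of moving each parameter by `{-step, 0, +step}`,
#' clipped to bounds and deduplicated.
#'
#' @param state numeric vector of current values (one per definition).
#' @param defs list of [hyperparam] definitions.
#' @return matrix of candidate states (rows).
#' @export
propose_mesh <- function(state, defs) {
  if (!length(defs)) stop_invalid("need at least one hyperparameter")
  offs <- lapply(defs, function(d) c(-d$step, 0, d$step))
  grid <- as.matrix(expand.grid(offs))
  cand <- sweep(grid, 2L, state, "+")
  cand <- apply(cand, 1L, clip_state, defs = defs)
  cand <- if (length(defs) == 1L) matrix(cand, ncol = 1L) else t(cand)
  colnames(cand) <- vapply(defs, `[[`, "", "name")
  unique(cand)
}

#' Coordinate-direction candidates
#'
#' The current point plus one move of `+-step` along each coordinate
#' (`2N + 1` candidates before clipping/deduplication).
#'
#' @inheritParams propose_mesh
#' @return matrix of candidate states (rows), current state first.
#' @export
propose_coordinate <- function(state, defs) {
  if (!length(defs)) stop_invalid("need at least one hyperparameter")
  N <- length(defs)
  cand <- matrix(rep(state, 2L * N + 1L), ncol = N, byrow = TRUE)
  for (k in seq_len(N)) {
    cand[2L * k, k] <- state[k] - defs[[k]]$step
    cand[2L * k + 1L, k] <- state[k] + defs[[k]]$step
  }
  cand <- apply(cand, 1L, clip_state, defs = defs)
  cand <- if (length(defs) == 1L) matrix(cand, ncol = 1L) else t(cand)
  colnames(cand) <- vapply(defs, `[[`, "", "name")
  unique(cand)
}

#' Stochastic hyperparameter search
#'
#' Per iteration, candidate states are generated around the incumbent
#' (hypercubic mesh or coordinate directions) and each candidate's
#' objective is evaluated on a fresh, independently drawn minibatch.
#' Integer parameters jump to the best candidate; real parameters take a
#' gradient-ascent step along the finite-difference slope with step size
#' `learning_rate * max(|value|, 1)`. Ties keep the current state. The
#' search stops at `n_iter` iterations or earlier when the incumbent has
#' not changed for `plateau` consecutive iterations.
#'
#' @param objective function `(state, minibatch) -> numeric` to maximize;
#'   `state` is a named numeric vector, `minibatch` an integer vector of
#'   data indices (or `NULL` when `n_data` is `NULL`).
#' @param defs list of [hyperparam] definitions.
#' @param n_iter iteration budget.
#' @param minibatch_size number of data indices drawn per evaluation.
#' @param n_data size of the data pool to draw minibatches from (`NULL`
#'   passes `minibatch = NULL`, i.e. full-data evaluation).
#' @param seed integer seed for minibatch draws.
#' @param mode `"mesh"` or `"coordinate"`.
#' @param learning_rate relative step factor for real-parameter updates.
#' @param plateau consecutive unchanged iterations before early stop.
#' @return object of class `tune_trajectory`: `states` (iterations x
#'   parameters), `objectives`, `accepted`, `best_state`, `best_objective`.
#' @export
sgd_tune <- function(objective, defs, n_iter = 50L, minibatch_size = NULL,
                     n_data = NULL, seed = 1L,
                     mode = c("mesh", "coordinate"),
                     learning_rate = 0.1, plateau = 10L) {
  mode <- match.arg(mode)
  n_iter <- check_count(n_iter, "n_iter")
  state <- clip_state(vapply(defs, `[[`, numeric(1), "init"), defs)
  names(state) <- vapply(defs, `[[`, "", "name")
  kinds <- vapply(defs, `[[`, "", "kind")
  traj_states <- matrix(NA_real_, n_iter, length(defs),
                        dimnames = list(NULL, names(state)))
  traj_obj <- numeric(n_iter)
  accepted <- logical(n_iter)
  best_state <- state; best_obj <- -Inf
  seeds <- derive_seeds(seed, n_iter)
  unchanged <- 0L
  it_done <- 0L
  for (it in seq_len(n_iter)) {
    cand <- if (mode == "mesh") propose_mesh(state, defs)
            else propose_coordinate(state, defs)
    vals <- local_seed(seeds[it], vapply(seq_len(nrow(cand)), function(r) {
      mb <- if (is.null(n_data)) NULL
            else sample.int(n_data, min(minibatch_size, n_data))
      v <- objective(stats::setNames(cand[r, ], names(state)), mb)
      if (!is.finite(v)) {
        warning("objective returned a non-finite value; candidate discarded")
        v <- -Inf
      }
      v
    }, numeric(1)))
    cur_row <- which(apply(cand, 1L, function(r) all(r == state)))[1L]
    cur_val <- if (!is.na(cur_row)) vals[cur_row] else -Inf
    best_row <- which.max(vals)
    new_state <- state
    moved <- FALSE
    if (vals[best_row] > cur_val) {
      if (any(kinds == "integer")) {
        new_state[kinds == "integer"] <- cand[best_row, kinds == "integer"]
      }
      for (k in which(kinds == "real")) {
        # finite-difference slope along coordinate k from candidates that
        # differ from the incumbent only in k
        only_k <- apply(cand, 1L, function(r)
          all(r[-k] == state[-k]) && r[k] != state[k])
        if (any(only_k)) {
          dk <- cand[only_k, k] - state[k]
          slope <- sum((vals[only_k] - cur_val) * dk) / sum(dk^2)
          if (is.finite(slope))
            new_state[k] <- state[k] +
              learning_rate * max(abs(state[k]), 1) * slope
        }
      }
      new_state <- clip_state(new_state, defs)
      moved <- !all(new_state == state)
    }
    accepted[it] <- moved
    state <- new_state
    it_val <- max(vals[is.finite(vals)], cur_val)
    traj_states[it, ] <- state
    traj_obj[it] <- it_val
    if (it_val > best_obj) { best_obj <- it_val; best_state <- state }
    unchanged <- if (moved) 0L else unchanged + 1L
    it_done <- it
    if (unchanged >= plateau) break
  }
  structure(list(states = traj_states[seq_len(it_done), , drop = FALSE],
                 objectives = traj_obj[seq_len(it_done)],
                 accepted = accepted[seq_len(it_done)],
                 best_state = best_state, best_objective = best_obj,
                 mode = mode, seed = seed),
            class = "tune_trajectory")
}

#' @export
print.tune_trajectory <- function(x, ...) {
  cat(sprintf("<tune_trajectory> %d iteration(s), best objective %.4g at (%s)\n",
              nrow(x$states), x$best_objective,
              paste(sprintf("%s=%g", names(x$best_state), x$best_state),
                    collapse = ", ")))
  invisible(x)
}
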
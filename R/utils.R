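# Internal helpers: classed errors, seed scoping, tolerant pseudo-inverse.

pem_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pembench_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

stop_invalid <- function(msg) pem_stop(msg, "pembench_invalid_parameter")
stop_samples <- function(msg) pem_stop(msg, "pembench_insufficient_samples")
stop_degenerate <- function(msg) pem_stop(msg, "pembench_degenerate_signal")
stop_numeric <- function(msg) pem_stop(msg, "pembench_numerical_degeneracy")
stop_format <- function(msg) pem_stop(msg, "pembench_format_error")
stop_shape <- function(msg) pem_stop(msg, "pembench_shape_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state, so every generator in the package is a
#' pure function of its arguments and seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw `n` sub-seeds (< 2^31) deterministically from a root seed.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Tolerance-truncated pseudo-inverse solve
#'
#' Solves `A x = b` in the least-squares sense through the singular-value
#' decomposition, truncating singular values below `tol` times the largest.
#'
#' @param A numeric matrix.
#' @param b numeric vector or matrix of right-hand sides.
#' @param tol relative truncation tolerance (default 1e-10).
#' @return solution vector/matrix.
#' @keywords internal
pinv_solve <- function(A, b, tol = 1e-10) {
  s <- svd(A)
  b <- as.matrix(b)
  keep <- s$d > tol * max(s$d[1], 0)
  if (!any(keep)) return(matrix(0, ncol(A), ncol(b)))
  s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], b) / s$d[keep])
}

# Moore–Penrose pseudo-inverse with the same truncation rule.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d[1], 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

spectral_radius <- function(A) {
  if (length(A) == 0L) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x))
    stop_invalid(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}
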
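#' Multichannel recording
#'
#' The basic data container: an `n` channels by `N` time-samples numeric
#' matrix with a sampling interval in seconds and optional channel labels.
#' Every predictor in the package consumes and produces recordings (or lists
#' of them, treated as independent segments whose lags never cross segment
#' boundaries).
#'
#' @param values numeric matrix, channels in rows, time in columns. A numeric
#'   vector is treated as a single channel.
#' @param sampling_interval seconds per sample (positive).
#' @param labels optional character vector of channel names.
#' @return an object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(20), 2), sampling_interval = 0.72)
#' dim(rec)
#' @export
recording <- function(values, sampling_interval = 1, labels = NULL) {
  if (is.vector(values) && is.numeric(values))
    values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop_shape("'values' must be a numeric matrix (channels x time)")
  if (ncol(values) < 2L)
    stop_samples("a recording needs at least 2 time samples")
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      !is.finite(sampling_interval) || sampling_interval <= 0)
    stop_invalid("'sampling_interval' must be a single positive number")
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nrow(values)))
  }
  if (length(labels) != nrow(values))
    stop_shape("'labels' length must equal the number of channels")
  rownames(values) <- labels
  structure(list(values = values,
                 sampling_interval = sampling_interval,
                 labels = labels),
            class = "recording")
}

#' @export
dim.recording <- function(x) dim(x$values)

#' @export
as.matrix.recording <- function(x, ...) x$values

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples, dt = %g s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  invisible(x)
}

n_channels <- function(x) nrow(x$values)
n_samples <- function(x) ncol(x$values)

# Coerce a recording / matrix / list thereof to a list of recordings.
as_segments <- function(x) {
  if (inherits(x, "recording")) return(list(x))
  if (is.matrix(x)) return(list(recording(x)))
  if (is.list(x))
    return(lapply(x, function(s) if (inherits(s, "recording")) s
                  else recording(s)))
  stop_shape("expected a recording, a matrix, or a list of them")
}

assert_clean <- function(segments) {
  for (s in segments)
    if (!all(is.finite(s$values)))
      stop_degenerate("recording contains non-finite values; see filter_nan_segments()")
  invisible(TRUE)
}

#' Number of samples spanned by a duration
#'
#' Discretization arithmetic: a duration in seconds at a fixed sampling
#' interval corresponds to `round(duration / dt)` samples (for instance 864 s
#' at 0.72 s per sample gives 1200 samples).
#'
#' @param duration_s duration in seconds.
#' @param sampling_interval seconds per sample.
#' @return integer number of samples.
#' @export
samples_for_duration <- function(duration_s, sampling_interval) {
  if (duration_s <= 0 || sampling_interval <= 0)
    stop_invalid("duration and sampling interval must be positive")
  as.integer(round(duration_s / sampling_interval))
}

#' Drop segments containing non-finite entries
#'
#' Data-hygiene filter: any segment with at least one NaN, NA or infinite
#' value is removed before model fitting; the indices of dropped segments are
#' reported.
#'
#' @param segments list of recordings or numeric matrices.
#' @return list with components `kept` (list of clean segments) and
#'   `dropped` (integer indices of removed segments).
#' @export
filter_nan_segments <- function(segments) {
  if (inherits(segments, "recording") || is.matrix(segments))
    segments <- list(segments)
  ok <- vapply(segments, function(s) {
    v <- if (inherits(s, "recording")) s$values else s
    all(is.finite(v))
  }, logical(1))
  if (!any(ok))
    pem_stop("all segments contain non-finite values", "pembench_empty_input")
  dropped <- which(!ok)
  if (length(dropped))
    message(sprintf("filter_nan_segments: dropped segment(s) %s",
                    paste(dropped, collapse = ", ")))
  list(kept = segments[ok], dropped = dropped)
}
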
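#' Read and write recordings
#'
#' Two on-disk representations are supported. `"delimited"` is tab-separated
#' text with a header row of channel labels, one row per channel; it round
#' trips to at least 1e-12 relative accuracy. `"binary"` is a raw
#' little-endian double array that round trips bit exactly. Both formats
#' carry a JSON sidecar (`<path>.json`) holding the sampling interval,
#' channel labels and matrix dimensions.
#'
#' @param rec a [recording].
#' @param path file path.
#' @param format `"delimited"` or `"binary"`.
#' @return `read_recording` returns a [recording]; `write_recording` returns
#'   `path` invisibly.
#' @examples
#' rec <- recording(matrix(rnorm(12), 3), sampling_interval = 0.5)
#' f <- tempfile(fileext = ".tsv")
#' write_recording(rec, f)
#' rec2 <- read_recording(f)
#' @export
write_recording <- function(rec, path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "recording"))
  sidecar <- list(sampling_interval = rec$sampling_interval,
                  labels = rec$labels,
                  n_channels = nrow(rec$values),
                  n_samples = ncol(rec$values),
                  format = format,
                  package = "pembench")
  if (format == "delimited") {
    tab <- t(rec$values)
    colnames(tab) <- rec$labels
    utils::write.table(format(tab, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(rec$values), con, size = 8L, endian = "little")
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (format == "delimited") {
    lines <- readLines(path)
    if (length(lines) < 3L) stop_format("delimited recording needs a header and >= 2 rows")
    labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
    widths <- lengths(cells)
    if (any(widths != length(labels)))
      stop_format(sprintf("ragged row %d: %d cells, expected %d",
                          which(widths != length(labels))[1L] + 1L,
                          widths[widths != length(labels)][1L], length(labels)))
    vals <- suppressWarnings(
      vapply(cells, function(r) as.numeric(r), numeric(length(labels))))
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop_format(sprintf("non-numeric cell at row %d, column %d ('%s')",
                          bad[2L] + 1L, bad[1L],
                          cells[[bad[2L]]][bad[1L]]))
    }
    values <- if (is.matrix(vals)) vals else matrix(vals, nrow = 1L)
  } else {
    if (is.null(meta))
      stop_format("binary recording requires its JSON sidecar")
    con <- file(path, "rb")
    on.exit(close(con))
    values <- matrix(readBin(con, "double",
                             n = meta$n_channels * meta$n_samples,
                             size = 8L, endian = "little"),
                     nrow = meta$n_channels)
    labels <- meta$labels
  }
  si <- if (!is.null(meta$sampling_interval)) meta$sampling_interval else 1
  if (is.null(meta) || is.null(meta$sampling_interval))
    stop_format("missing sampling interval: provide the JSON sidecar")
  recording(values, sampling_interval = si,
            labels = if (format == "delimited") labels else meta$labels)
}
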
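#' Uniformly sampled time series
#'
#' The common currency of the pipeline: a scalar or multi-channel signal
#' sampled at a fixed rate. Values are stored as a numeric matrix with one
#' column per channel; a scalar series has one column.
#'
#' @param values numeric vector or matrix (rows = samples, cols = channels).
#' @param rate sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds.
#' @param unit measurement unit label (e.g. "N", "mm", "px").
#' @param confidence optional per-sample confidence in \[0, 1\], a vector or a
#'   matrix matching `values` (used for pose-estimation keypoints).
#' @return an object of class `sampled_series`.
#' @export
sampled_series <- function(values, rate, start = 0, unit = "", confidence = NULL) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0, is.finite(start))
  if (!is.null(confidence)) {
    if (is.null(dim(confidence))) confidence <- matrix(confidence, ncol = ncol(values))
    stopifnot(nrow(confidence) == nrow(values))
  }
  structure(list(values = values, rate = as.numeric(rate), start = as.numeric(start),
                 unit = unit, confidence = confidence),
            class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("<sampled_series> %d samples x %d channel(s) @ %g Hz [%s], t = [%.3f, %.3f] s\n",
              n_samples(x), ncol(x$values), x$rate,
              if (nzchar(x$unit)) x$unit else "unitless",
              x$start, x$start + (n_samples(x) - 1) / x$rate))
  invisible(x)
}

#' Number of samples in a series
#' @param x a `sampled_series`.
#' @export
n_samples <- function(x) nrow(x$values)

#' Sample times of a series
#' @param x a `sampled_series`.
#' @return numeric vector of times in seconds.
#' @export
series_time <- function(x) x$start + (seq_len(n_samples(x)) - 1) / x$rate

#' Extract one channel of a series as a plain vector
#' @param x a `sampled_series`.
#' @param channel column name or index (default first).
#' @export
series_values <- function(x, channel = 1L) {
  as.numeric(x$values[, channel])
}

#' Replace the values of a series, keeping its time base
#' @param x a `sampled_series`.
#' @param values replacement vector/matrix with the same number of rows.
#' @keywords internal
set_values <- function(x, values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  stopifnot(nrow(values) == n_samples(x))
  colnames(values) <- colnames(x$values)[seq_len(ncol(values))]
  x$values <- values
  x
}

#' Extract a sample window of a series
#' @param x a `sampled_series`.
#' @param from,to first and last sample index (1-based, inclusive).
#' @export
series_window <- function(x, from, to) {
  stopifnot(from >= 1L, to <= n_samples(x), from <= to)
  sampled_series(x$values[from:to, , drop = FALSE], rate = x$rate,
                 start = x$start + (from - 1L) / x$rate, unit = x$unit,
                 confidence = if (!is.null(x$confidence)) x$confidence[from:to, , drop = FALSE])
}

#' Convert image-down pixel coordinates to up-positive
#'
#' Image y grows downward; all rescaling assumes up-positive series, so the
#' sign is inverted exactly once, here. The additive image origin is
#' irrelevant to every downstream quantity (displacements, minmax, parabola
#' curvature), so no offset is applied.
#'
#' @param x a `sampled_series` in pixel (image-down) coordinates.
#' @return the series with all channels negated.
#' @export
px_to_up <- function(x) set_values(x, -x$values)

# run a block with a private, restored RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
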
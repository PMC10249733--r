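#' Remove pose-estimation spikes by first-difference z-scores
#'
#' Pose-estimation false detections appear as spike runs of one or two
#' frames: a large first difference into the run undone by a large,
#' nearly-cancelling difference of the opposite sign out of it. Frames
#' between such a pair of differences (at most two apart, opposite-signed
#' z-scores beyond `z_thresh`, sum small against the larger of the two) are
#' flagged and replaced by linear interpolation from the flanking inlier
#' frames; all other samples are unchanged. z-scores use the median and MAD
#' of the differences so the spikes themselves do not inflate the scale,
#' and the cancellation requirement keeps genuine fast motion — whose large
#' differences are same-signed or unbalanced — untouched. The pass repeats
#' up to three times. Indices of replaced frames are attached as attribute
#' `spike_idx` (a list, one integer vector per channel).
#'
#' @param series a `sampled_series` (length >= 5).
#' @param z_thresh z-score threshold on first differences.
#' @return the despiked series.
#' @export
remove_spikes_zscore <- function(series, z_thresh = 3) {
  stopifnot(inherits(series, "sampled_series"), n_samples(series) >= 5)
  vals <- series$values
  spike_idx <- vector("list", ncol(vals))
  for (ch in seq_len(ncol(vals))) {
    x <- vals[, ch]
    all_bad <- integer()
    for (pass in 1:3) {
      d <- diff(x)
      # local running-median trend captures genuine motion (piecewise-
      # monotone differences have zero residual), leaving spikes isolated
      k <- min(7L, length(d) - (1 - length(d) %% 2))
      r <- if (k >= 3) d - stats::runmed(d, k) else d - stats::median(d)
      s <- stats::mad(r)
      if (!is.finite(s) || s == 0) s <- stats::sd(r)
      if (!is.finite(s) || s == 0) break
      z <- r / s
      # a spike run (at most two frames) enters on a large difference and
      # exits on a large difference of the opposite sign; genuine fast
      # motion produces large same-signed differences instead
      big <- which(abs(z) > z_thresh)
      bad <- integer()
      for (a in big) {
        mates <- big[big > a & big <= a + 2L & sign(z[big]) == -sign(z[a]) &
                       abs(z[big] + z[a]) < 0.5 * pmax(abs(z[big]), abs(z[a]))]
        if (length(mates)) bad <- c(bad, (a + 1L):min(mates))
      }
      bad <- sort(unique(bad[bad >= 1L & bad <= length(x)]))
      if (!length(bad)) break
      all_bad <- union(all_bad, bad)
      if (length(all_bad) >= length(x) / 2)
        stop("all frames flagged as spikes; series unusable")
      good <- setdiff(seq_along(x), bad)
      x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
    }
    vals[, ch] <- x
    spike_idx[[ch]] <- sort(all_bad)
  }
  out <- set_values(series, vals)
  attr(out, "spike_idx") <- spike_idx
  out
}

#' Repair marker-occlusion dropouts
#'
#' Optical-marker coordinates drop to exactly zero when a marker is occluded
#' by hands or clothing. Runs of exact zeros in a series whose typical
#' magnitude is far from zero are treated as missing and replaced by linear
#' interpolation across the run (constant extrapolation at the edges).
#'
#' @param series a `sampled_series` in mm.
#' @param min_magnitude minimum typical |value| for zeros to count as
#'   dropouts rather than data.
#' @return the repaired series.
#' @export
repair_dropouts <- function(series, min_magnitude = 10) {
  vals <- series$values
  for (ch in seq_len(ncol(vals))) {
    x <- vals[, ch]
    if (stats::median(abs(x)) < min_magnitude) next
    bad <- which(x == 0)
    if (!length(bad) || length(bad) >= length(x)) next
    good <- setdiff(seq_along(x), bad)
    x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
    vals[, ch] <- x
  }
  set_values(series, vals)
}

#' Savitzky-Golay smoothing
#'
#' Second-order polynomial least-squares smoothing over a sliding window
#' (default 21 samples). Reproduces quadratic signals exactly, so the
#' parabolic flight arc is preserved when the window fits inside it. Edges
#' are handled by evaluating the full-window polynomial fit off-centre
#' (as `signal::sgolayfilt` does), which is likewise exact for quadratics.
#'
#' @param series a `sampled_series`.
#' @param window filter window length, samples (odd, >= order + 1).
#' @param order polynomial order.
#' @return the smoothed series.
#' @export
smooth_savgol <- function(series, window = 21, order = 2) {
  stopifnot(inherits(series, "sampled_series"))
  if (n_samples(series) < window)
    stop(sprintf("series length %d < Savitzky-Golay window %d", n_samples(series), window))
  vals <- series$values
  for (ch in seq_len(ncol(vals)))
    vals[, ch] <- signal::sgolayfilt(vals[, ch], p = order, n = window)
  set_values(series, vals)
}

# peak prominence: height above the higher of the two deepest valleys
# separating the peak from higher terrain (or the series edge) on each side
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- if (p > 1) x[1:(p - 1)] else numeric()
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric()
    hi_l <- which(left >= x[p])
    base_l <- if (length(hi_l)) min(x[(max(hi_l) + 1):p]) else min(c(left, x[p]))
    hi_r <- which(right >= x[p])
    base_r <- if (length(hi_r)) min(x[p:(p + min(hi_r) - 1)]) else min(c(right, x[p]))
    x[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Segment jump repetitions around hip peaks
#'
#' Each repetition is identified by the dominant peak of the (denoised,
#' up-positive) hip series — the maximum height attained in flight — and a
#' window of `window_t` seconds is taken to either side of each peak.
#' Peaks must have prominence of at least `prominence_frac` of the global
#' range and be at least `2 * window_t` apart (the more prominent of two
#' close peaks is kept). Segments clipped by the series bounds are flagged.
#'
#' @param hip a denoised up-positive hip `sampled_series` (single channel).
#' @param window_t half-window to either side of each peak, s.
#' @param prominence_frac minimum peak prominence, fraction of global range.
#' @return list of `jump_segment` objects (fields `peak_index`,
#'   `start_index`, `end_index`, `rep_id`, `qc_flags`); empty for a flat
#'   series.
#' @export
segment_repetitions <- function(hip, window_t = 1.5, prominence_frac = 0.5) {
  stopifnot(inherits(hip, "sampled_series"), window_t > 0)
  x <- series_values(hip, 1L)
  n <- length(x)
  rng <- diff(range(x))
  if (rng <= 0) return(list())
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L   # local maxima
  if (!length(cand)) return(list())
  prom <- peak_prominence(x, cand)
  keep <- cand[prom >= prominence_frac * rng]
  promk <- prom[prom >= prominence_frac * rng]
  if (!length(keep)) return(list())
  # enforce minimum inter-peak distance, keeping the more prominent
  min_dist <- round(2 * window_t * hip$rate)
  ord <- order(promk, decreasing = TRUE)
  sel <- logical(length(keep))
  for (i in ord) {
    if (any(sel & abs(keep - keep[i]) < min_dist)) next
    sel[i] <- TRUE
  }
  peaks <- sort(keep[sel])
  w <- round(window_t * hip$rate)
  out <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    s0 <- p - w; e0 <- p + w
    flags <- character()
    if (s0 < 1L || e0 > n) flags <- "clipped_window"
    out[[i]] <- jump_segment(peak_index = p, start_index = max(1L, s0),
                             end_index = min(n, e0), rep_id = i, qc_flags = flags)
  }
  out
}

#' One repetition window around a hip peak
#'
#' @param peak_index,start_index,end_index sample indices into the parent
#'   series (start <= peak <= end).
#' @param rep_id repetition number.
#' @param qc_flags character subset of
#'   {"spiky", "low_confidence", "uncharacteristic", "clipped_window"}.
#' @export
jump_segment <- function(peak_index, start_index, end_index, rep_id,
                         qc_flags = character()) {
  stopifnot(start_index <= peak_index, peak_index <= end_index)
  structure(list(peak_index = as.integer(peak_index),
                 start_index = as.integer(start_index),
                 end_index = as.integer(end_index),
                 rep_id = as.integer(rep_id),
                 qc_flags = qc_flags),
            class = "jump_segment")
}

#' @export
print.jump_segment <- function(x, ...) {
  cat(sprintf("<jump_segment> rep %d: [%d, %d], peak %d%s\n", x$rep_id,
              x$start_index, x$end_index, x$peak_index,
              if (length(x$qc_flags)) paste0(" flags: ", paste(x$qc_flags, collapse = ",")) else ""))
  invisible(x)
}

#' Flag uncharacteristic or low-confidence repetitions
#'
#' A valid countermovement jump shows a single dominant hip peak inside its
#' window. The `uncharacteristic` flag is set when >= 2 distinct bumps rise
#' above `rel_peak` of the apex-to-baseline displacement (bumps count as
#' distinct only when separated by a valley returning below 30% of that
#' displacement), or when the downward excursion below the segment baseline
#' exceeds `max_drop` (the countermovement bound, in the units of `hip`). `low_confidence` is set when the median keypoint
#' confidence over the window falls below `conf_threshold`. `spiky` is set
#' when more than `spike_frac` of the window's frames were replaced during
#' spike removal (pass the `spike_idx` attribute of
#' [remove_spikes_zscore()]).
#'
#' @param segment a `jump_segment`.
#' @param hip the up-positive hip `sampled_series` the segment indexes.
#' @param confidence optional per-frame confidence vector for the series.
#' @param spike_idx optional integer vector of despiked frame indices.
#' @param rel_peak relative height for competing-maxima detection.
#' @param conf_threshold median-confidence threshold.
#' @param max_drop countermovement bound (same units as `hip`); `Inf` skips.
#' @param spike_frac spiky-flag threshold, fraction of window frames.
#' @return the segment with `qc_flags` updated.
#' @export
flag_uncharacteristic <- function(segment, hip, confidence = NULL,
                                  spike_idx = NULL, rel_peak = 0.7,
                                  conf_threshold = 0.3, max_drop = Inf,
                                  spike_frac = 0.05) {
  stopifnot(inherits(segment, "jump_segment"))
  idx <- segment$start_index:segment$end_index
  x <- series_values(hip, 1L)[idx]
  flags <- segment$qc_flags
  rng <- diff(range(x))
  if (rng > 0) {
    nwin <- max(1L, round(0.5 * hip$rate))
    baseline <- stats::median(x[seq_len(min(nwin, length(x)))])
    amp <- max(x) - baseline
    d <- diff(x)
    cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    # competing bumps: local maxima rising above rel_peak of the apex
    # displacement, separated by a valley that returns below 30% of it —
    # measured against the baseline, not the raw range, so the
    # countermovement dip cannot mask them and noise wiggles on a single
    # apex cannot mimic them
    if (length(cand) && amp > 0) {
      high <- cand[x[cand] >= baseline + rel_peak * amp]
      valley <- baseline + 0.3 * amp
      n_bumps <- 0L
      anchor <- NULL
      for (p in high) {
        if (is.null(anchor) || min(x[anchor:p]) < valley) {
          n_bumps <- n_bumps + 1L
          anchor <- p
        }
      }
      if (n_bumps >= 2L) flags <- union(flags, "uncharacteristic")
    }
    if (is.finite(max_drop) && baseline - min(x) > max_drop)
      flags <- union(flags, "uncharacteristic")
  }
  if (!is.null(confidence) &&
      stats::median(confidence[idx], na.rm = TRUE) < conf_threshold)
    flags <- union(flags, "low_confidence")
  if (!is.null(spike_idx) &&
      sum(spike_idx %in% idx) / length(idx) > spike_frac)
    flags <- union(flags, "spiky")
  segment$qc_flags <- flags
  segment
}

#' Fourier-domain resampling to a target length
#'
#' Band-limited (FFT) resampling: the discrete spectrum of the input is
#' zero-padded to the target length and inverse-transformed, exactly as
#' Fourier resampling of a periodic signal. Upsampling only; the mean (DC
#' component) is preserved to floating tolerance. The output rate is scaled
#' by `target_len / n` so the series spans the same duration.
#'
#' @param series a `sampled_series`.
#' @param target_len desired number of samples (>= current length).
#' @return the resampled series.
#' @export
resample_to_length <- function(series, target_len) {
  stopifnot(inherits(series, "sampled_series"))
  n <- n_samples(series)
  target_len <- as.integer(target_len)
  if (target_len < n) stop("resample_to_length upsamples only (target_len < length)")
  if (target_len == n) return(series)
  vals <- series$values
  out <- matrix(0, target_len, ncol(vals), dimnames = list(NULL, colnames(vals)))
  for (ch in seq_len(ncol(vals))) {
    X <- stats::fft(vals[, ch])
    Y <- complex(real = numeric(target_len))
    half <- n %/% 2
    if (n %% 2 == 0) {
      # split the Nyquist bin symmetrically so the output stays real
      Y[1:half] <- X[1:half]
      Y[half + 1L] <- X[half + 1L] / 2
      Y[target_len - half + 1L] <- Conj(X[half + 1L]) / 2
      if (half > 1) Y[(target_len - half + 2L):target_len] <- X[(half + 2L):n]
    } else {
      Y[1:(half + 1L)] <- X[1:(half + 1L)]
      Y[(target_len - half + 1L):target_len] <- X[(half + 2L):n]
    }
    out[, ch] <- Re(stats::fft(Y, inverse = TRUE)) / n
  }
  conf <- if (!is.null(series$confidence)) {
    # confidence is not band-limited; carry it by nearest-neighbour
    src <- pmin(n, 1L + floor((seq_len(target_len) - 1L) * n / target_len))
    series$confidence[src, , drop = FALSE]
  }
  sampled_series(out, rate = series$rate * target_len / n, start = series$start,
                 unit = series$unit, confidence = conf)
}
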
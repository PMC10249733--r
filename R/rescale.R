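#' Reverse-minmax rescaling of a pixel series onto a metric reference
#'
#' The pixel series is minmax-normalised to \[0, 1\] and mapped onto the
#' range of the metric reference series:
#' `q* = (q - min q) / (max q - min q)`, then
#' `q_mm = q* (max p - min p) + min p`. The output's minimum and maximum
#' equal the reference's exactly, which is why this rescaling requires the
#' optical-marker reference and is usable for evaluation only — it cannot
#' run from a single camera alone.
#'
#' @param q_px pixel `sampled_series` (single channel, up-positive — the
#'   caller applies the sign convention; see [px_to_up()]).
#' @param p_mm metric reference `sampled_series` of equal length (resample
#'   first; see [resample_to_length()]).
#' @return a `sampled_series` in mm on `q_px`'s time base.
#' @export
rescale_rmm <- function(q_px, p_mm) {
  stopifnot(inherits(q_px, "sampled_series"), inherits(p_mm, "sampled_series"))
  q <- series_values(q_px, 1L)
  p <- series_values(p_mm, 1L)
  if (!length(q) || !length(p)) stop("empty series")
  if (length(q) != length(p)) stop("series lengths differ; resample first")
  if (max(q) - min(q) <= 0) stop("degenerate pixel range: constant pixel series")
  if (max(p) - min(p) <= 0) stop("degenerate reference range: constant reference series")
  qs <- (q - min(q)) / (max(q) - min(q))
  out <- set_values(q_px, qs * (max(p) - min(p)) + min(p))
  out$unit <- "mm"
  out
}

#' Pixel-to-metric scale estimate
#'
#' @param R scale in mm per px.
#' @param free_fall_T free-fall window duration, s.
#' @param pixel_drop |d0 - dT| in px.
#' @param source "fitted" or "cohort_mean_fallback".
#' @export
scale_estimate <- function(R, free_fall_T = NA_real_, pixel_drop = NA_real_,
                           source = c("fitted", "cohort_mean_fallback")) {
  source <- match.arg(source)
  stopifnot(is.finite(R), R > 0)
  structure(list(R = R, free_fall_T = free_fall_T, pixel_drop = pixel_drop,
                 source = source),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("<scale_estimate> R = %.4f mm/px (%s; T = %.3f s, drop = %.1f px)\n",
              x$R, x$source, x$free_fall_T, x$pixel_drop))
  invisible(x)
}

#' Estimate the pixel-to-metric scale from gravitational free fall
#'
#' During flight the hip is in free fall, so in up-positive pixels it traces
#' a parabola with curvature -g/2 divided by the scale. Using gravity as the
#' physical reference: after a free fall of T seconds from the apex (where
#' velocity is zero) the body descends 500 T^2 g millimetres, and the same
#' descent measured on the image is |d0 - dT| pixels, hence
#' 1 px = R mm with `R = 500 T^2 g / |d0 - dT|`.
#'
#' The apex position and time are refined below frame resolution by a
#' least-squares parabola fitted to the airborne hip samples (those above
#' `baseline + (1 - alpha)` of the apex displacement, a window that by
#' construction stays inside the flight phase); at 30 fps a frame-quantised
#' apex would alone mis-time the short free-fall window by up to half a
#' frame. The free-fall window runs from the fitted apex to the last frame
#' before the hip has descended a fraction `alpha` of its apex-to-baseline
#' displacement; d0 and dT are read off the fitted arc.
#'
#' @param hip_px denoised, up-positive hip pixel `sampled_series`.
#' @param segment the repetition's `jump_segment`.
#' @param alpha fraction of the apex-to-baseline displacement spanned by the
#'   free-fall window.
#' @param baseline_window leading quiet-stance window for the baseline, s.
#' @param min_drop_px resolution floor on |d0 - dT|; below it the estimate
#'   is declared not estimable (error of class `cmjump_not_estimable`) and
#'   the caller should fall back to [cohort_mean_fallback()].
#' @param g gravitational acceleration, m/s^2.
#' @return a `scale_estimate` with source "fitted".
#' @export
estimate_ptm_scale <- function(hip_px, segment, alpha = 0.5,
                               baseline_window = 0.5, min_drop_px = 2,
                               g = GRAVITY) {
  stopifnot(inherits(hip_px, "sampled_series"), inherits(segment, "jump_segment"))
  not_estimable <- function(msg)
    stop(structure(class = c("cmjump_not_estimable", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  idx <- segment$start_index:segment$end_index
  x <- series_values(hip_px, 1L)[idx]
  tt <- (idx - 1) / hip_px$rate
  nb <- max(1L, round(baseline_window * hip_px$rate))
  baseline <- stats::median(x[seq_len(min(nb, length(x)))])
  apex_i <- which.max(x)
  amp <- x[apex_i] - baseline
  if (amp <= min_drop_px) not_estimable("hip displacement too small to calibrate")
  thr <- baseline + (1 - alpha) * amp
  # contiguous airborne run around the apex
  above <- x >= thr
  a <- apex_i; while (a > 1L && above[a - 1L]) a <- a - 1L
  b <- apex_i; while (b < length(x) && above[b + 1L]) b <- b + 1L
  run <- a:b
  if (length(run) < 3L) not_estimable("too few airborne frames for the free-fall fit")
  fit <- stats::lm.fit(cbind(1, tt[run], tt[run]^2), x[run])
  c2 <- fit$coefficients[3]; c1 <- fit$coefficients[2]; c0 <- fit$coefficients[1]
  if (!is.finite(c2) || c2 >= 0) not_estimable("airborne hip samples are not concave")
  t_apex <- -c1 / (2 * c2)
  if (t_apex < tt[a] - 1 / hip_px$rate || t_apex > tt[b] + 1 / hip_px$rate)
    not_estimable("fitted apex falls outside the airborne window")
  q <- function(t) c0 + c1 * t + c2 * t^2
  T_ff <- tt[b] - t_apex
  if (T_ff <= 0) not_estimable("no descending free-fall frames after the apex")
  drop <- q(t_apex) - q(tt[b])
  if (drop < min_drop_px) not_estimable("pixel drop below resolution floor")
  scale_estimate(R = 500 * T_ff^2 * g / drop, free_fall_T = T_ff,
                 pixel_drop = drop, source = "fitted")
}

#' Apply a pixel-to-metric scale
#'
#' q_mm = R * q_px, applied to every sample (the up-positive sign convention
#' must already have been applied upstream, once).
#'
#' @param q_px pixel `sampled_series`.
#' @param scale a `scale_estimate` (or a positive number).
#' @return a mm-scale `sampled_series`.
#' @export
apply_scale <- function(q_px, scale) {
  R <- if (inherits(scale, "scale_estimate")) scale$R else as.numeric(scale)
  stopifnot(is.finite(R), R > 0)
  out <- set_values(q_px, q_px$values * R)
  out$unit <- "mm"
  out
}

#' Cohort-mean fallback scale
#'
#' When a repetition's own free-fall calibration fails (pose-estimation
#' failure cases), the mean fitted R over the remaining estimates is used
#' instead.
#'
#' @param estimates list of `scale_estimate` objects.
#' @return a `scale_estimate` with source "cohort_mean_fallback".
#' @export
cohort_mean_fallback <- function(estimates) {
  fitted <- Filter(function(e) inherits(e, "scale_estimate") && e$source == "fitted",
                   estimates)
  if (!length(fitted)) stop("no fitted scale estimates available for fallback")
  scale_estimate(R = mean(vapply(fitted, `[[`, numeric(1), "R")),
                 source = "cohort_mean_fallback")
}
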
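#' Jump height from flight time
#'
#' h = 100 g Tf^2 / 8 (cm): during a jump whose toe-off and landing heights
#' coincide, the body rises for Tf/2 under gravity, so the apex is
#' g (Tf/2)^2 / 2 metres above take-off.
#'
#' @param Tf flight time in seconds (vectorised).
#' @param g gravitational acceleration, m/s^2.
#' @return jump height in centimetres.
#' @export
height_from_flight_time <- function(Tf, g = GRAVITY) {
  if (any(!is.finite(Tf)) || any(Tf < 0)) stop("flight time must be finite and >= 0")
  100 * g * Tf^2 / 8
}

#' Detect flight intervals in a vertical force trace
#'
#' Candidate flight regions are maximal runs where the force drops below a
#' fraction (default 5%) of the mean force over a leading quiet-stance
#' window. Each run's boundaries are then refined against the noise band of
#' the unloaded plate: starting from the run's interior, the interval is
#' grown to the last samples that stay within mean +/- k * sd of the
#' unloaded noise (sd estimated from the central 50% of the run), moving at
#' most `refine_window` seconds beyond the raw threshold crossing. Runs
#' shorter than `min_flight` are discarded as chatter.
#'
#' @param force a `sampled_series` of vertical force (N), rate >= 100 Hz.
#' @param stance_window leading quiet-stance window used for the baseline, s.
#' @param threshold_frac unloading threshold as a fraction of stance force.
#' @param k_sd half-width of the unloaded-noise band in sd units.
#' @param min_flight minimum plausible flight duration, s.
#' @param refine_window maximum boundary refinement beyond the raw
#'   threshold crossing, s.
#' @return data.frame with one row per repetition: `rep_id`,
#'   `toe_off_index` (first unloaded sample), `landing_index` (first loaded
#'   sample after flight), and `flight_time_Tf` =
#'   (landing_index - toe_off_index) / rate. Empty (0-row) if no flight.
#' @export
detect_flight_intervals <- function(force, stance_window = 0.5,
                                    threshold_frac = 0.05, k_sd = 5,
                                    min_flight = 0.08, refine_window = 0.05) {
  stopifnot(inherits(force, "sampled_series"))
  if (force$rate < 100) stop("force rate must be >= 100 Hz")
  f <- series_values(force, 1L)
  n <- length(f)
  n_st <- round(stance_window * force$rate)
  if (n_st < 2 || n_st > n) stop("stance baseline not estimable: stance_window out of range")
  baseline <- mean(f[seq_len(n_st)])
  if (!is.finite(baseline) || baseline <= 0)
    stop("stance baseline not estimable: non-positive leading force")
  thr <- threshold_frac * baseline

  below <- f < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- NULL
  rep_id <- 0L
  max_ext <- round(refine_window * force$rate)
  for (ri in runs) {
    s0 <- starts[ri]; e0 <- ends[ri]
    len <- e0 - s0 + 1L
    if (len / force$rate < min_flight) next
    # unloaded noise band from the central 50% of the run
    core <- s0 + floor(len / 4):ceiling(3 * len / 4 - 1)
    core <- core[core >= s0 & core <= e0]
    mu <- mean(f[core]); sd0 <- stats::sd(f[core])
    band <- max(k_sd * sd0, 1e-9)
    inband <- abs(f - mu) <= band
    # a departure must be sustained to count as a force change: bridge
    # isolated out-of-band noise samples (< 3 ms) back into the band
    m_consec <- max(1L, round(0.003 * force$rate))
    ob <- rle(!inband)
    short_out <- ob$values & ob$lengths < m_consec
    if (any(short_out)) {
      ob$values[short_out] <- FALSE
      inband <- !inverse.rle(ob)
    }
    # grow outward from the run centre, at most max_ext past the raw crossing
    mid <- s0 + len %/% 2
    a <- mid
    while (a > max(1L, s0 - max_ext) && inband[a - 1L]) a <- a - 1L
    b <- mid
    while (b < min(n, e0 + max_ext) && inband[b + 1L]) b <- b + 1L
    Tf <- (b - a + 1L) / force$rate
    if (Tf < min_flight) next
    rep_id <- rep_id + 1L
    out <- rbind(out, data.frame(rep_id = rep_id, toe_off_index = a,
                                 landing_index = b + 1L, flight_time_Tf = Tf))
  }
  if (is.null(out))
    out <- data.frame(rep_id = integer(), toe_off_index = integer(),
                      landing_index = integer(), flight_time_Tf = numeric())
  out
}

#' Force-plate jump heights for a recording
#'
#' Convenience wrapper: detect flight intervals and convert each flight time
#' to a height.
#'
#' @param force a `sampled_series` of vertical force.
#' @param ... forwarded to [detect_flight_intervals()].
#' @return data.frame `rep_id`, `flight_time_Tf`, `height_cm`.
#' @export
force_plate_heights <- function(force, ...) {
  fi <- detect_flight_intervals(force, ...)
  fi$height_cm <- height_from_flight_time(fi$flight_time_Tf)
  fi[, c("rep_id", "flight_time_Tf", "height_cm")]
}
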
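#' Specification of a synthetic countermovement jump recording
#'
#' Defines one participant-task capture: the true jump kinematics and the
#' imperfections of the three recording modalities (force plate at 1000 Hz,
#' optical marker capture at 100 Hz, single-camera keypoints at 30 fps).
#'
#' @param true_height true jump height in cm (>= 0; 0 means a countermovement
#'   with no lift-off).
#' @param body_mass body mass in kg.
#' @param n_reps number of jump repetitions.
#' @param task "bilateral" or "unilateral".
#' @param countermovement_depth depth of the pre-jump dip in cm.
#' @param stance_duration quiet standing before the first countermovement, s.
#' @param rest_between_reps quiet standing between repetitions, s.
#' @param scale_R_true true pixel-to-metric scale, mm per px.
#' @param pixel_noise_sd white noise on keypoint pixel coordinates, px.
#' @param marker_noise_sd white noise on marker coordinates, mm.
#' @param force_noise_sd white noise on the force trace, N.
#' @param spike_prob per-frame probability of an isolated pose-estimation
#'   spike (a single frame displaced by >= 20 * pixel_noise_sd).
#' @param failure_mode "none", "limb_swap" (hip and toe keypoints swapped for
#'   a sustained window in each rep), or "uncharacteristic" (the keypoint
#'   trajectory is replaced by a non-jump meander, as produced by a failed
#'   pose estimate).
#' @param rep_heights optional per-repetition true heights in cm (length
#'   `n_reps`); defaults to `true_height` for every rep.
#' @param seed RNG seed used by [simulate_recording()].
#' @return a validated `jump_spec` object.
#' @export
jump_spec <- function(true_height = 20, body_mass = 70, n_reps = 3,
                      task = c("bilateral", "unilateral"),
                      countermovement_depth = 25, stance_duration = 2,
                      rest_between_reps = 1.5, scale_R_true = 3.43,
                      pixel_noise_sd = 1, marker_noise_sd = 1,
                      force_noise_sd = 2, spike_prob = 0.01,
                      failure_mode = c("none", "limb_swap", "uncharacteristic"),
                      rep_heights = NULL, seed = 1L) {
  task <- match.arg(task)
  failure_mode <- match.arg(failure_mode)
  if (!is.numeric(true_height) || true_height < 0 || !is.finite(true_height))
    stop("true_height must be a non-negative finite number (cm)")
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("body_mass must be positive (kg)")
  stopifnot(n_reps >= 1, countermovement_depth >= 0, stance_duration > 0,
            rest_between_reps >= 0, scale_R_true > 0, pixel_noise_sd >= 0,
            marker_noise_sd >= 0, force_noise_sd >= 0,
            spike_prob >= 0, spike_prob <= 1)
  if (is.null(rep_heights)) rep_heights <- rep(true_height, n_reps)
  stopifnot(length(rep_heights) == n_reps, all(rep_heights >= 0))
  structure(list(true_height = true_height, body_mass = body_mass,
                 n_reps = as.integer(n_reps), task = task,
                 countermovement_depth = countermovement_depth,
                 stance_duration = stance_duration,
                 rest_between_reps = rest_between_reps,
                 scale_R_true = scale_R_true, pixel_noise_sd = pixel_noise_sd,
                 marker_noise_sd = marker_noise_sd, force_noise_sd = force_noise_sd,
                 spike_prob = spike_prob, failure_mode = failure_mode,
                 rep_heights = rep_heights, seed = as.integer(seed)),
            class = "jump_spec")
}

GRAVITY <- 9.81          # m/s^2
HIP_BASELINE_M <- 0.95   # standing hip height
TOE_BASELINE_M <- 0.03   # standing fifth-metatarsal height
COM_BASELINE_M <- 1.00   # standing centre-of-mass height
IMAGE_ORIGIN_PX <- 600   # image row of the world origin (y grows downward)
CM_DURATION_S <- 0.6     # countermovement dip duration
ABSORB_DURATION_S <- 0.15
RECOVER_DURATION_S <- 0.4

#' Flight time implied by a jump height
#'
#' Inverse of the flight-time height formula h = 100 g Tf^2 / 8: a jump of
#' h cm has flight time sqrt(8 h / (100 g)) s.
#'
#' @param height_cm jump height in cm.
#' @param g gravitational acceleration, m/s^2.
#' @export
flight_time_from_height <- function(height_cm, g = GRAVITY) {
  stopifnot(all(height_cm >= 0))
  sqrt(8 * height_cm / (100 * g))
}

# one analytic motion segment: phase label, [t0, t1), and closures giving
# COM displacement s(tau) [m] and acceleration a(tau) [m/s^2]
motion_segment <- function(phase, t0, t1, s, a) {
  list(phase = phase, t0 = t0, t1 = t1, s = s, a = a)
}

# build the piecewise-analytic segment table for one recording.
# Raised-cosine countermovement and propulsion profiles keep the trajectory
# twice differentiable everywhere except the toe-off/landing force steps.
# The apex of every rep is snapped onto the 0.1 s grid (a common multiple of
# the 1000 Hz, 100 Hz and 30 fps sample grids) by stretching the preceding
# quiet stance, so all three modalities sample the true apex exactly.
build_segments <- function(spec) {
  g <- GRAVITY
  segs <- list()
  reps <- data.frame(rep_id = integer(), height_cm = numeric(),
                     t_toe_off = numeric(), t_apex = numeric(),
                     t_land = numeric())
  t <- 0
  for (r in seq_len(spec$n_reps)) {
    h <- spec$rep_heights[r] / 100                       # m
    D <- spec$countermovement_depth / 100                # m
    lead <- if (r == 1) spec$stance_duration else spec$rest_between_reps
    if (h > 0) {
      v0 <- sqrt(2 * g * h)
      Tf <- 2 * v0 / g
      Deff <- max(D, 0.01)                               # propulsion needs travel
      Tcm <- CM_DURATION_S
      Tp <- 2 * Deff / v0
      t_apex_nom <- t + lead + Tcm + Tp + Tf / 2
      pad <- ceiling(t_apex_nom / 0.1 + 1e-9) * 0.1 - t_apex_nom
      lead <- lead + pad
      t_cm <- t + lead
      t_bot <- t_cm + Tcm
      t_to <- t_bot + Tp
      t_land <- t_to + Tf
      t_abs <- t_land + ABSORB_DURATION_S
      t_rec <- t_abs + RECOVER_DURATION_S
      A <- v0 * ABSORB_DURATION_S / 2                    # absorption depth
      segs <- c(segs, list(
        motion_segment("stance", t, t_cm, function(u) 0 * u, function(u) 0 * u),
        local({
          Tcm_ <- Tcm; Deff_ <- Deff
          motion_segment("countermovement", t_cm, t_bot,
            function(u) -Deff_ / 2 * (1 - cos(pi * u / Tcm_)),
            function(u) -Deff_ / 2 * (pi / Tcm_)^2 * cos(pi * u / Tcm_))
        }),
        local({
          Tp_ <- Tp; Deff_ <- Deff; v0_ <- v0
          motion_segment("propulsion", t_to - Tp_, t_to,
            function(u) -Deff_ + v0_ / 2 * (u - Tp_ / pi * sin(pi * u / Tp_)),
            function(u) v0_ * pi / (2 * Tp_) * sin(pi * u / Tp_))
        }),
        local({
          v0_ <- v0
          motion_segment("flight", t_to, t_land,
            function(u) v0_ * u - GRAVITY * u^2 / 2,
            function(u) rep(-GRAVITY, length(u)))
        }),
        local({
          Tl_ <- ABSORB_DURATION_S; v0_ <- v0
          motion_segment("landing", t_land, t_abs,
            function(u) -v0_ / 2 * (u + Tl_ / pi * sin(pi * u / Tl_)),
            function(u) v0_ * pi / (2 * Tl_) * sin(pi * u / Tl_))
        }),
        local({
          Tr_ <- RECOVER_DURATION_S; A_ <- A
          motion_segment("landing", t_abs, t_rec,
            function(u) -A_ / 2 * (1 + cos(pi * u / Tr_)),
            function(u) A_ / 2 * (pi / Tr_)^2 * cos(pi * u / Tr_))
        })))
      reps <- rbind(reps, data.frame(rep_id = r, height_cm = spec$rep_heights[r],
                                     t_toe_off = t_to, t_apex = t_to + Tf / 2,
                                     t_land = t_land))
      t <- t_rec
    } else {
      # no lift-off: dip and smooth return only
      Tcm <- CM_DURATION_S
      Tp0 <- 0.4
      t_cm <- t + lead
      t_bot <- t_cm + Tcm
      t_up <- t_bot + Tp0
      segs <- c(segs, list(
        motion_segment("stance", t, t_cm, function(u) 0 * u, function(u) 0 * u),
        local({
          Tcm_ <- Tcm; D_ <- D
          motion_segment("countermovement", t_cm, t_bot,
            function(u) -D_ / 2 * (1 - cos(pi * u / Tcm_)),
            function(u) -D_ / 2 * (pi / Tcm_)^2 * cos(pi * u / Tcm_))
        }),
        local({
          Tp0_ <- Tp0; D_ <- D
          motion_segment("propulsion", t_bot, t_up,
            function(u) -D_ / 2 * (1 + cos(pi * u / Tp0_)),
            function(u) D_ / 2 * (pi / Tp0_)^2 * cos(pi * u / Tp0_))
        })))
      reps <- rbind(reps, data.frame(rep_id = r, height_cm = spec$rep_heights[r],
                                     t_toe_off = NA_real_, t_apex = NA_real_,
                                     t_land = NA_real_))
      t <- t_up
    }
  }
  segs <- c(segs, list(motion_segment("stance", t, t + spec$rest_between_reps + 0.5,
                                      function(u) 0 * u, function(u) 0 * u)))
  list(segments = segs, reps = reps, t_end = t + spec$rest_between_reps + 0.5)
}

# evaluate the analytic motion at arbitrary times
eval_motion <- function(built, t, body_mass) {
  n <- length(t)
  s <- numeric(n); a <- numeric(n)
  phase <- rep("stance", n)
  last <- length(built$segments)
  for (i in seq_along(built$segments)) {
    sg <- built$segments[[i]]
    idx <- if (i == last) which(t >= sg$t0 - 1e-12) else which(t >= sg$t0 - 1e-12 & t < sg$t1 - 1e-12)
    if (!length(idx)) next
    u <- t[idx] - sg$t0
    s[idx] <- sg$s(u)
    a[idx] <- sg$a(u)
    phase[idx] <- sg$phase
  }
  force <- body_mass * (GRAVITY + a)
  force[phase == "flight"] <- 0
  toe <- rep(TOE_BASELINE_M, n)
  fl <- phase == "flight"
  toe[fl] <- TOE_BASELINE_M + s[fl]
  list(time = t,
       com_height = COM_BASELINE_M + s,
       hip_height = HIP_BASELINE_M + s,
       toe_height = toe,
       vertical_force = pmax(force, 0),
       phase = factor(phase, levels = c("stance", "countermovement", "propulsion",
                                        "flight", "landing")))
}

#' Simulate ground-truth countermovement-jump motion
#'
#' Builds a piecewise-analytic vertical trajectory: quiet stance, a
#' raised-cosine countermovement dip, a raised-cosine-velocity propulsion
#' phase ending at take-off velocity, ballistic free flight whose apex
#' exceeds the stance baseline by exactly the true height, a brief landing
#' absorption and recovery, and rest. The toe (fifth metatarsal) stays at
#' its stance height except in flight, where it translates with the body.
#'
#' @param spec a [jump_spec()].
#' @param rate sampling rate of the returned grid, Hz (>= 1000 recommended).
#' @return a `jump_motion` object: time grid, COM/hip/toe heights (m),
#'   vertical force (N, exactly 0 in flight), per-sample phase labels, a
#'   repetition table (`$reps`) with toe-off/apex/landing times, and the
#'   analytic segment table used by the renderers.
#' @export
simulate_motion <- function(spec, rate = 1000) {
  stopifnot(inherits(spec, "jump_spec"), rate > 0)
  built <- build_segments(spec)
  t <- seq(0, built$t_end, by = 1 / rate)
  ev <- eval_motion(built, t, spec$body_mass)
  structure(c(ev, list(rate = rate, reps = built$reps, built = built, spec = spec)),
            class = "jump_motion")
}

#' @export
print.jump_motion <- function(x, ...) {
  cat(sprintf("<jump_motion> %d reps, %.1f s @ %g Hz; true heights: %s cm\n",
              nrow(x$reps), max(x$time), x$rate,
              paste(round(x$reps$height_cm, 2), collapse = ", ")))
  invisible(x)
}

#' Render a motion as a 1000 Hz force-plate trace
#'
#' @param motion a `jump_motion`.
#' @param spec the generating [jump_spec()] (noise parameters).
#' @param rate output rate, Hz.
#' @return a `sampled_series` (channel `force`, N). Noise is added on the
#'   whole trace, including the unloaded flight segments.
#' @export
render_force_plate <- function(motion, spec, rate = 1000) {
  t <- seq(0, motion$built$t_end, by = 1 / rate)
  ev <- eval_motion(motion$built, t, spec$body_mass)
  f <- ev$vertical_force
  if (spec$force_noise_sd > 0) f <- f + stats::rnorm(length(f)) * spec$force_noise_sd
  out <- sampled_series(f, rate = rate, unit = "N")
  colnames(out$values) <- "force"
  out
}

#' Render a motion as 100 Hz optical-marker trajectories
#'
#' @param motion a `jump_motion`.
#' @param spec the generating [jump_spec()].
#' @param rate output rate, Hz.
#' @param dropout if TRUE, inject brief drop-to-zero runs mimicking marker
#'   occlusion by hands or clothing.
#' @param dropout_prob per-sample probability that a dropout run starts.
#' @param dropout_duration dropout run length, s.
#' @return a `sampled_series` with channels `hip` and `toe` (mm, up-positive).
#' @export
render_omc <- function(motion, spec, rate = 100, dropout = FALSE,
                       dropout_prob = 0.002, dropout_duration = 0.08) {
  t <- seq(0, motion$built$t_end, by = 1 / rate)
  ev <- eval_motion(motion$built, t, spec$body_mass)
  vals <- cbind(hip = ev$hip_height * 1000, toe = ev$toe_height * 1000)
  if (spec$marker_noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(vals)), ncol = 2) * spec$marker_noise_sd
  if (dropout) {
    n <- nrow(vals)
    len <- max(1L, round(dropout_duration * rate))
    for (ch in 1:2) {
      starts <- which(stats::runif(n) < dropout_prob)
      if (!length(starts)) starts <- sample.int(n - len, 1L)
      for (s0 in starts) vals[s0:min(n, s0 + len - 1L), ch] <- 0
    }
  }
  sampled_series(vals, rate = rate, unit = "mm")
}

#' Render a motion as 30 fps pose-estimation keypoints
#'
#' Pixel coordinates follow the image convention (y grows downward):
#' `px = origin - mm / scale_R_true`. Imperfections: white pixel noise,
#' isolated spike frames (displacement >= 20 * pixel_noise_sd, confidence
#' dropped), and the selected `failure_mode`.
#'
#' @param motion a `jump_motion`.
#' @param spec the generating [jump_spec()].
#' @param fps frame rate.
#' @return a `sampled_series` with channels `hip` and `toe` (px, image-down)
#'   and per-frame confidence.
#' @export
render_mmc <- function(motion, spec, fps = 30) {
  t <- seq(0, motion$built$t_end, by = 1 / fps)
  ev <- eval_motion(motion$built, t, spec$body_mass)
  n <- length(t)
  mm <- cbind(hip = ev$hip_height * 1000, toe = ev$toe_height * 1000)
  if (spec$failure_mode == "uncharacteristic") {
    # failed pose estimate: repeated equal-height bumps instead of the
    # single dominant per-rep peak of a real jump
    wob <- 150 * sin(2 * pi * 0.4 * t)^2
    mm[, "hip"] <- HIP_BASELINE_M * 1000 + wob
    mm[, "toe"] <- TOE_BASELINE_M * 1000 + 0.6 * wob
  }
  px <- IMAGE_ORIGIN_PX - mm / spec$scale_R_true
  conf <- matrix(0.9, n, 2, dimnames = list(NULL, c("hip", "toe")))
  if (spec$pixel_noise_sd > 0)
    px <- px + matrix(stats::rnorm(2 * n), ncol = 2) * spec$pixel_noise_sd
  if (spec$spike_prob > 0) {
    # draw all auxiliary variates up-front so the RNG call sequence does not
    # depend on which frames spike (keeps matched-seed runs comparable)
    hit <- matrix(stats::runif(2 * n) < spec$spike_prob, ncol = 2)
    mag <- matrix(stats::runif(2 * n, 1, 2), ncol = 2) *
      max(20 * spec$pixel_noise_sd, 30)
    sgn <- matrix(sign(stats::runif(2 * n) - 0.5), ncol = 2)
    px[hit] <- px[hit] + (mag * sgn)[hit]
    conf[hit] <- 0.2
  }
  if (spec$failure_mode == "limb_swap" && nrow(motion$reps) > 0) {
    # sustained hip/toe identity swap for ~0.5 s around each apex
    for (r in seq_len(nrow(motion$reps))) {
      ta <- motion$reps$t_apex[r]
      if (is.na(ta)) next
      idx <- which(t >= ta - 0.25 & t <= ta + 0.25)
      px[idx, c(1, 2)] <- px[idx, c(2, 1)]
      conf[idx, ] <- 0.4
    }
  }
  sampled_series(px, rate = fps, unit = "px", confidence = conf)
}

#' Simulate one full synchronized recording
#'
#' Renders one underlying motion through all three modalities with the
#' spec's seed governing every noise draw; identical spec + seed gives
#' bit-identical output.
#'
#' @param spec a [jump_spec()].
#' @param dropout forward to [render_omc()].
#' @return a `jump_recording`: `$spec`, `$motion`, `$force`, `$omc`, `$mmc`,
#'   and `$truth` (per-rep true heights and event times).
#' @export
simulate_recording <- function(spec, dropout = FALSE) {
  motion <- simulate_motion(spec)
  rec <- with_seed(spec$seed, {
    force <- render_force_plate(motion, spec)
    omc <- render_omc(motion, spec, dropout = dropout)
    mmc <- render_mmc(motion, spec)
    list(force = force, omc = omc, mmc = mmc)
  })
  structure(list(spec = spec, motion = motion, force = rec$force,
                 omc = rec$omc, mmc = rec$mmc, truth = motion$reps),
            class = "jump_recording")
}

#' @export
print.jump_recording <- function(x, ...) {
  cat(sprintf("<jump_recording> task=%s, %d reps, seed=%d\n",
              x$spec$task, x$spec$n_reps, x$spec$seed))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Draws participant mean heights from a truncated normal and per-rep heights
#' with small repetition-to-repetition jitter, then renders each participant's
#' recording. Defaults mirror a bilateral countermovement-jump session:
#' 16 adults, 3 reps, cohort mean ~21 cm with ~9 cm between-subject spread.
#'
#' @param n_participants,n_reps cohort size.
#' @param task "bilateral" or "unilateral".
#' @param height_mean,height_sd between-subject height distribution, cm.
#' @param rep_jitter_sd within-subject rep-to-rep height jitter, cm.
#' @param seed master seed; per-participant seeds are derived from it.
#' @param ... overrides forwarded to [jump_spec()] (noise levels etc.).
#' @return list with `$recordings` (list of `jump_recording`) and `$truth`
#'   (data.frame participant, rep_id, true height).
#' @export
simulate_cohort <- function(n_participants = 16, n_reps = 3,
                            task = "bilateral", height_mean = 21,
                            height_sd = 8.8, rep_jitter_sd = 0.5,
                            seed = 1L, ...) {
  with_seed(seed, {
    recs <- vector("list", n_participants)
    truth <- NULL
    for (i in seq_len(n_participants)) {
      repeat {
        H <- stats::rnorm(1, height_mean, height_sd)
        if (H >= 5 && H <= 55) break
      }
      hr <- pmax(3, H + stats::rnorm(n_reps) * rep_jitter_sd)
      pseed <- sample.int(.Machine$integer.max - 1L, 1L)
      sp <- jump_spec(true_height = H, n_reps = n_reps, task = task,
                      rep_heights = hr, seed = pseed, ...)
      recs[[i]] <- simulate_recording(sp)
      truth <- rbind(truth, data.frame(participant = sprintf("P%02d", i),
                                       rep_id = seq_len(n_reps),
                                       true_height_cm = hr))
    }
    list(recordings = recs, truth = truth)
  })
}
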
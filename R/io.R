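#' Write a force trace as CSV
#'
#' Columns `time_s`, `force_N`; the sampling rate is declared in a leading
#' `# rate_hz=` comment line rather than inferred from the time stamps.
#'
#' @param force a `sampled_series` (N).
#' @param path output file.
#' @export
write_force_csv <- function(force, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g", force$rate), con)
  utils::write.csv(data.frame(time_s = series_time(force),
                              force_N = series_values(force, 1L)),
                   con, row.names = FALSE)
  invisible(path)
}

read_rate_header <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*rate_hz=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stop("missing '# rate_hz=' header line in ", path)
  as.numeric(m[2])
}

#' Read a force CSV
#' @param path file written by [write_force_csv()] (or the same dialect).
#' @return a `sampled_series` (channel `force`, N).
#' @export
read_force_csv <- function(path) {
  rate <- read_rate_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "force_N") %in% names(df)))
    stop("force CSV must have columns time_s, force_N")
  out <- sampled_series(df$force_N, rate = rate, start = df$time_s[1], unit = "N")
  colnames(out$values) <- "force"
  out
}

#' Write marker trajectories as CSV
#'
#' Columns `time_s` plus one `<marker>_z_mm` column per channel; rate in a
#' `# rate_hz=` header line.
#'
#' @param omc a `sampled_series` (mm) with named channels.
#' @param path output file.
#' @export
write_marker_csv <- function(omc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g", omc$rate), con)
  df <- data.frame(time_s = series_time(omc))
  for (ch in colnames(omc$values)) df[[paste0(ch, "_z_mm")]] <- omc$values[, ch]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a marker CSV
#'
#' @param path file in the [write_marker_csv()] dialect.
#' @param hip,toe names of the columns holding the hip and fifth-metatarsal
#'   vertical coordinates (which cluster marker maps to "hip" is rig
#'   specific, hence configurable).
#' @return a `sampled_series` (mm) with channels `hip`, `toe`.
#' @export
read_marker_csv <- function(path, hip = "hip_z_mm", toe = "toe_z_mm") {
  rate <- read_rate_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", hip, toe) %in% names(df)))
    stop("marker CSV lacks required columns: time_s, ", hip, ", ", toe)
  sampled_series(cbind(hip = df[[hip]], toe = df[[toe]]), rate = rate,
                 start = df$time_s[1], unit = "mm")
}

BODY25_MIDHIP <- 8L
BODY25_RSMALLTOE <- 23L

#' Write keypoints as pose-estimation JSON
#'
#' Consolidated OpenPose body-25 dialect: an object with `fps` and a
#' `frames` array; each frame holds a `people` array whose entries carry 75
#' `pose_keypoints_2d` values (x, y, confidence per keypoint). The hip and
#' toe channels are written into the MidHip (8) and RSmallToe (23) slots;
#' all other keypoints get zero confidence.
#'
#' @param mmc a `sampled_series` with channels `hip` and `toe` (px,
#'   image-down) and confidence.
#' @param path output file.
#' @param image_x constant image x coordinate written for each keypoint.
#' @export
write_keypoints_json <- function(mmc, path, image_x = 360) {
  n <- n_samples(mmc)
  conf <- if (!is.null(mmc$confidence)) mmc$confidence else matrix(1, n, 2)
  frames <- lapply(seq_len(n), function(i) {
    kp <- numeric(75)
    for (slot in list(c(BODY25_MIDHIP, 1), c(BODY25_RSMALLTOE, 2))) {
      j <- slot[1] * 3
      kp[j + 1] <- image_x
      kp[j + 2] <- mmc$values[i, slot[2]]
      kp[j + 3] <- conf[i, slot[2]]
    }
    list(people = list(list(pose_keypoints_2d = kp)))
  })
  jsonlite::write_json(list(fps = mmc$rate, frames = frames), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read pose-estimation keypoint JSON
#'
#' Reads the consolidated body-25 dialect of [write_keypoints_json()]. When
#' a frame contains several detected people, the person with the highest
#' mean keypoint confidence is kept (with a warning). Frames with no
#' detection yield NA coordinates and zero confidence.
#'
#' @param path JSON file.
#' @param hip_keypoint,toe_keypoint body-25 indices (0-based) of the hip and
#'   fifth-metatarsal keypoints.
#' @return a `sampled_series` with channels `hip`, `toe` (px, image-down)
#'   and per-frame confidence.
#' @export
read_keypoints_json <- function(path, hip_keypoint = BODY25_MIDHIP,
                                toe_keypoint = BODY25_RSMALLTOE) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$frames) || !length(doc$frames)) stop("empty frame list in ", path)
  fps <- if (!is.null(doc$fps)) as.numeric(doc$fps) else 30
  n <- length(doc$frames)
  vals <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("hip", "toe")))
  conf <- matrix(0, n, 2, dimnames = list(NULL, c("hip", "toe")))
  multi <- FALSE
  for (i in seq_len(n)) {
    people <- doc$frames[[i]]$people
    if (is.null(people) || !length(people)) next
    kps <- lapply(people, function(p) as.numeric(unlist(p$pose_keypoints_2d)))
    bad <- which(vapply(kps, length, integer(1)) != 75)
    if (length(bad))
      stop(sprintf("frame %d: person with %d keypoint values (expected 75)",
                   i, length(kps[[bad[1]]])))
    if (length(kps) > 1) {
      multi <- TRUE
      mc <- vapply(kps, function(k) mean(k[seq(3, 75, by = 3)]), numeric(1))
      kps <- kps[which.max(mc)]
    }
    k <- kps[[1]]
    vals[i, 1] <- k[hip_keypoint * 3 + 2]; conf[i, 1] <- k[hip_keypoint * 3 + 3]
    vals[i, 2] <- k[toe_keypoint * 3 + 2]; conf[i, 2] <- k[toe_keypoint * 3 + 3]
  }
  if (multi) warning("frames with multiple detected people: kept the highest-confidence person")
  sampled_series(vals, rate = fps, unit = "px", confidence = conf)
}

#' Session analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with validation, and
#' round-trips losslessly through YAML.
#'
#' @param task "bilateral" or "unilateral".
#' @param window_t segmentation half-window, s.
#' @param savgol_window,savgol_order Savitzky-Golay parameters.
#' @param z_thresh spike-removal z threshold.
#' @param alpha PTM free-fall window fraction.
#' @param conf_threshold low-confidence QC threshold.
#' @param prominence_frac peak prominence fraction for segmentation.
#' @param min_flight minimum plausible flight time, s.
#' @param stance_window force-plate stance baseline window, s.
#' @param baseline_window toe/hip baseline window, s.
#' @param min_drop_px PTM pixel-drop resolution floor.
#' @param fallback "cohort_mean" or "none" (failed PTM calibrations error).
#' @param seed RNG seed for any stochastic step.
#' @export
session_config <- function(task = "bilateral", window_t = 1.5,
                           savgol_window = 21, savgol_order = 2,
                           z_thresh = 3, alpha = 0.5, conf_threshold = 0.3,
                           prominence_frac = 0.5, min_flight = 0.08,
                           stance_window = 0.5, baseline_window = 0.5,
                           min_drop_px = 2, fallback = c("cohort_mean", "none"),
                           seed = 1L) {
  fallback <- match.arg(fallback)
  stopifnot(task %in% c("bilateral", "unilateral"), window_t > 0,
            savgol_window %% 2 == 1, savgol_window > savgol_order,
            z_thresh > 0, alpha > 0, alpha <= 1,
            conf_threshold >= 0, conf_threshold <= 1,
            prominence_frac > 0, prominence_frac <= 1,
            min_flight > 0, stance_window > 0, baseline_window > 0,
            min_drop_px > 0)
  structure(list(task = task, window_t = window_t,
                 savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order), z_thresh = z_thresh,
                 alpha = alpha, conf_threshold = conf_threshold,
                 prominence_frac = prominence_frac, min_flight = min_flight,
                 stance_window = stance_window, baseline_window = baseline_window,
                 min_drop_px = min_drop_px, fallback = fallback,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Write a session configuration to YAML
#' @param config a `session_config`.
#' @param path output file.
#' @export
write_session_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a session configuration from YAML
#' @param path YAML file.
#' @export
read_session_config <- function(path) {
  do.call(session_config, yaml::read_yaml(path))
}
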
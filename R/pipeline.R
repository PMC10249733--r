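# failure-case flags exclude a repetition from the agreement statistics;
# "spiky" (smoothable spikes) and "clipped_window" are informational only
is_failure <- function(flags) any(flags %in% c("uncharacteristic", "low_confidence"))

#' Analyze one synchronized jump recording
#'
#' Runs the full measurement chain on whichever modalities are present:
#'
#' * force plate: flight-interval detection and flight-time height ("FP");
#' * optical markers: spike removal, Savitzky-Golay smoothing, hip-peak
#'   segmentation, toe-displacement height ("OMC");
#' * keypoints: spike removal at the native frame rate, segmentation on the
#'   smoothed hip, per-repetition QC flags, Fourier upsampling of each
#'   segment onto the 100 Hz time base, Savitzky-Golay smoothing there,
#'   then gravity-calibrated pixel-to-metric conversion ("MMC_PTM") and —
#'   when markers are present — reference-based reverse minmax ("MMC_RMM",
#'   evaluation only).
#'
#' Repetitions whose own free-fall calibration is not estimable fall back
#' to the mean fitted R of the recording (session-level pooling is applied
#' by [run_session()]). Per-repetition failures are logged, not fatal; the
#' call errors only if every repetition fails.
#'
#' @param rec a `jump_recording`, or a list with any of `force`, `omc`,
#'   `mmc` (`sampled_series`).
#' @param config a [session_config()].
#' @param participant participant label for the result rows.
#' @return list: `heights` (long data.frame: participant, task, method,
#'   rep_id, height_cm, excluded, flags), `scales` (per-rep
#'   `scale_estimate` or NULL), `ptm_px` (per-rep pixel-scale toe
#'   displacement, for deferred rescaling), `qc` (log data.frame).
#' @export
analyze_recording <- function(rec, config = session_config(), participant = "P01") {
  task <- if (inherits(rec, "jump_recording")) rec$spec$task else config$task
  qc <- data.frame(rep_id = integer(), stage = character(), message = character())
  log_qc <- function(rep_id, stage, message)
    qc <<- rbind(qc, data.frame(rep_id = rep_id, stage = stage, message = message))
  rows <- list()
  add_row <- function(method, rep_id, height_cm, excluded, flags)
    rows[[length(rows) + 1L]] <<- data.frame(
      participant = participant, task = task, method = method,
      rep_id = rep_id, height_cm = height_cm, excluded = excluded,
      flags = paste(flags, collapse = ";"))

  # --- force plate -------------------------------------------------------
  if (!is.null(rec$force)) {
    fp <- tryCatch(force_plate_heights(rec$force, stance_window = config$stance_window,
                                       min_flight = config$min_flight),
                   error = function(e) { log_qc(NA, "force", conditionMessage(e)); NULL })
    if (!is.null(fp))
      for (i in seq_len(nrow(fp)))
        add_row("FP", fp$rep_id[i], fp$height_cm[i], FALSE, character())
  }

  # --- optical markers ---------------------------------------------------
  omc_sm <- NULL; omc_segs <- list()
  if (!is.null(rec$omc)) {
    res <- tryCatch({
      de <- remove_spikes_zscore(repair_dropouts(rec$omc), config$z_thresh)
      sm <- smooth_savgol(de, config$savgol_window, config$savgol_order)
      segs <- segment_repetitions(
        sampled_series(sm$values[, "hip"], sm$rate, unit = "mm"),
        window_t = config$window_t, prominence_frac = config$prominence_frac)
      list(sm = sm, segs = segs)
    }, error = function(e) { log_qc(NA, "omc", conditionMessage(e)); NULL })
    if (!is.null(res)) {
      omc_sm <- res$sm; omc_segs <- res$segs
      toe <- sampled_series(omc_sm$values[, "toe"], omc_sm$rate, unit = "mm")
      for (sg in omc_segs) {
        h <- tryCatch(toe_displacement_height(toe, sg, config$baseline_window, "OMC"),
                      error = function(e) { log_qc(sg$rep_id, "omc_height", conditionMessage(e)); NULL })
        if (!is.null(h))
          add_row("OMC", sg$rep_id, h$height_cm, is_failure(sg$qc_flags), sg$qc_flags)
      }
    }
  }

  # --- markerless keypoints ---------------------------------------------
  scales <- list(); ptm_px <- list()
  if (!is.null(rec$mmc)) {
    res <- tryCatch({
      de <- remove_spikes_zscore(rec$mmc, config$z_thresh)
      spike_idx <- attr(de, "spike_idx")
      hip_sm <- smooth_savgol(
        sampled_series(de$values[, "hip"], de$rate, unit = "px"),
        config$savgol_window, config$savgol_order)
      hip_up <- px_to_up(hip_sm)
      segs <- segment_repetitions(hip_up, window_t = config$window_t,
                                  prominence_frac = config$prominence_frac)
      segs <- lapply(segs, function(sg)
        flag_uncharacteristic(sg, hip_up,
                              confidence = if (!is.null(de$confidence)) de$confidence[, "hip"],
                              spike_idx = spike_idx[[1]],
                              conf_threshold = config$conf_threshold))
      list(de = de, segs = segs)
    }, error = function(e) { log_qc(NA, "mmc", conditionMessage(e)); NULL })
    if (!is.null(res)) {
      de <- res$de
      for (sg in res$segs) {
        if (length(sg$qc_flags))
          log_qc(sg$rep_id, "mmc_qc", paste("flags:", paste(sg$qc_flags, collapse = ",")))
        seg_out <- tryCatch({
          win <- series_window(de, sg$start_index, sg$end_index)
          target <- round(n_samples(win) * 100 / win$rate)
          up <- resample_to_length(win, target)
          up <- smooth_savgol(up, config$savgol_window, config$savgol_order)
          hip100 <- px_to_up(sampled_series(up$values[, "hip"], up$rate, unit = "px"))
          toe100 <- px_to_up(sampled_series(up$values[, "toe"], up$rate, unit = "px"))
          whole <- jump_segment(which.max(series_values(hip100)), 1L,
                                n_samples(hip100), sg$rep_id, sg$qc_flags)
          # pixel-scale toe displacement, rescaled once R is known
          hpx <- tryCatch(toe_displacement_height(toe100, whole, config$baseline_window,
                                                  "px")$height_cm * 10,
                          error = function(e) NA_real_)
          sc <- tryCatch(estimate_ptm_scale(hip100, whole, alpha = config$alpha,
                                            baseline_window = config$baseline_window,
                                            min_drop_px = config$min_drop_px),
                         cmjump_not_estimable = function(e) {
                           log_qc(sg$rep_id, "ptm", conditionMessage(e)); NULL })
          rmm_h <- NA_real_
          if (!is.null(omc_sm) && length(omc_segs)) {
            # pair with the marker segment whose apex is nearest in time
            apex_t <- (sg$peak_index - 1) / de$rate
            omc_apex <- vapply(omc_segs, function(s) (s$peak_index - 1) / omc_sm$rate,
                               numeric(1))
            mate <- omc_segs[[which.min(abs(omc_apex - apex_t))]]
            if (abs(omc_apex[which.min(abs(omc_apex - apex_t))] - apex_t) <= config$window_t) {
              p_toe <- series_window(
                sampled_series(omc_sm$values[, "toe"], omc_sm$rate, unit = "mm"),
                mate$start_index, mate$end_index)
              q_toe <- resample_to_length(
                sampled_series(de$values[sg$start_index:sg$end_index, "toe"],
                               de$rate, unit = "px"), n_samples(p_toe))
              q_toe <- px_to_up(smooth_savgol(q_toe, config$savgol_window,
                                              config$savgol_order))
              q_mm <- rescale_rmm(q_toe, p_toe)
              whole_r <- jump_segment(which.max(series_values(q_mm)), 1L,
                                      n_samples(q_mm), sg$rep_id, sg$qc_flags)
              rmm_h <- toe_displacement_height(q_mm, whole_r, config$baseline_window,
                                               "MMC_RMM")$height_cm
            }
          }
          list(sc = sc, hpx = hpx, rmm_h = rmm_h)
        }, error = function(e) { log_qc(sg$rep_id, "mmc_rep", conditionMessage(e)); NULL })
        if (is.null(seg_out)) next
        scales[[as.character(sg$rep_id)]] <- seg_out$sc
        ptm_px[[as.character(sg$rep_id)]] <- seg_out$hpx
        excl <- is_failure(sg$qc_flags)
        if (!is.na(seg_out$rmm_h))
          add_row("MMC_RMM", sg$rep_id, seg_out$rmm_h, excl, sg$qc_flags)
        if (!is.null(seg_out$sc) && !is.na(seg_out$hpx))
          add_row("MMC_PTM", sg$rep_id, seg_out$sc$R * seg_out$hpx / 10, excl, sg$qc_flags)
      }
      # within-recording fallback for reps whose calibration failed
      fitted <- Filter(Negate(is.null), scales)
      if (length(fitted) && config$fallback == "cohort_mean") {
        fb <- cohort_mean_fallback(fitted)
        for (rid in names(ptm_px)) {
          if (!is.null(scales[[rid]]) || is.na(ptm_px[[rid]])) next
          sg <- Filter(function(s) s$rep_id == as.integer(rid), res$segs)[[1]]
          add_row("MMC_PTM", as.integer(rid), fb$R * ptm_px[[rid]] / 10,
                  is_failure(sg$qc_flags), sg$qc_flags)
          log_qc(as.integer(rid), "ptm", "used cohort_mean_fallback scale")
        }
      }
    }
  }

  heights <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(), task = character(), method = character(),
               rep_id = integer(), height_cm = numeric(), excluded = logical(),
               flags = character())
  if (!nrow(heights)) stop("all repetitions failed in every modality")
  list(heights = heights, scales = scales, ptm_px = ptm_px, qc = qc)
}

#' Run a full multi-participant session
#'
#' Analyzes each recording, pools the pixel-to-metric scale (per-repetition
#' R averaged within participant, participant means averaged across the
#' cohort), and computes method-agreement statistics over unflagged
#' repetitions: ICC(2,1) and Bland-Altman for each candidate/ground-truth
#' pair, plus per-method test-retest reliability across repetitions.
#'
#' @param recordings list of `jump_recording` (or modality lists), named or
#'   unnamed (participants are labelled P01, P02, ...).
#' @param config a [session_config()].
#' @param truth optional data.frame (`participant`, `rep_id`,
#'   `true_height_cm`); when given, agreement against simulated truth is
#'   also reported.
#' @return a `session_report`: `heights` (long), `table` (wide
#'   per-participant means), `mean_R`, `agreement` (list of
#'   `agreement_report` + ICCs per method pair), `trr` (test-retest ICC per
#'   method), `qc`.
#' @export
run_session <- function(recordings, config = session_config(), truth = NULL) {
  labels <- names(recordings)
  if (is.null(labels)) labels <- sprintf("P%02d", seq_along(recordings))
  heights <- NULL; qc <- NULL
  part_R <- numeric()
  for (i in seq_along(recordings)) {
    res <- analyze_recording(recordings[[i]], config, participant = labels[i])
    heights <- rbind(heights, res$heights)
    if (nrow(res$qc)) {
      res$qc$participant <- labels[i]
      qc <- rbind(qc, res$qc)
    }
    fitted <- Filter(Negate(is.null), res$scales)
    if (length(fitted))
      part_R[labels[i]] <- mean(vapply(fitted, `[[`, numeric(1), "R"))
  }
  mean_R <- if (length(part_R)) mean(part_R) else NA_real_

  tab <- summarize_per_participant(heights)
  pairs <- list(c("FP", "MMC_PTM"), c("FP", "MMC_RMM"),
                c("OMC", "MMC_PTM"), c("OMC", "MMC_RMM"))
  agreement <- list()
  wide <- heights_wide(heights)
  for (p in pairs) {
    gt <- p[1]; cand <- p[2]
    if (!all(c(gt, cand) %in% names(wide))) next
    ok <- stats::complete.cases(wide[[gt]], wide[[cand]])
    if (sum(ok) < 2) next
    nm <- paste0(cand, "_vs_", gt)
    agreement[[nm]] <- list(
      icc = icc_2_1(cbind(wide[[gt]][ok], wide[[cand]][ok])),
      bland_altman = bland_altman(wide[[cand]][ok], wide[[gt]][ok]))
  }
  if (!is.null(truth)) {
    wt <- merge(wide, truth, by = c("participant", "rep_id"), all.x = TRUE)
    for (m in intersect(c("FP", "OMC", "MMC_RMM", "MMC_PTM"), names(wt))) {
      ok <- stats::complete.cases(wt$true_height_cm, wt[[m]])
      if (sum(ok) < 2) next
      agreement[[paste0(m, "_vs_truth")]] <- list(
        icc = icc_2_1(cbind(wt$true_height_cm[ok], wt[[m]][ok])),
        bland_altman = bland_altman(wt[[m]][ok], wt$true_height_cm[ok]))
    }
  }
  trr <- list()
  for (m in unique(heights$method)) {
    sub <- heights[heights$method == m & !heights$excluded, ]
    if (!nrow(sub)) next
    mat <- stats::reshape(sub[, c("participant", "rep_id", "height_cm")],
                          idvar = "participant", timevar = "rep_id",
                          direction = "wide")
    mat <- as.matrix(mat[, -1, drop = FALSE])
    if (sum(stats::complete.cases(mat)) >= 2 && ncol(mat) >= 2)
      trr[[m]] <- icc_2_1(mat)
  }
  structure(list(heights = heights, table = tab, mean_R = mean_R,
                 agreement = agreement, trr = trr, qc = qc),
            class = "session_report")
}

# long (participant, method, rep_id, height) -> one row per participant x rep,
# one column per method; flagged repetitions become NA (listwise exclusion)
heights_wide <- function(heights) {
  h <- heights
  h$height_cm[h$excluded] <- NA_real_
  keys <- unique(h[, c("participant", "rep_id")])
  keys <- keys[order(keys$participant, keys$rep_id), , drop = FALSE]
  for (m in unique(h$method)) {
    sub <- h[h$method == m, c("participant", "rep_id", "height_cm")]
    names(sub)[3] <- m
    keys <- merge(keys, sub, by = c("participant", "rep_id"), all.x = TRUE)
  }
  keys[order(keys$participant, keys$rep_id), , drop = FALSE]
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d participants, %d height measurements; mean R = %.3f mm/px\n",
              length(unique(x$heights$participant)), nrow(x$heights), x$mean_R))
  for (nm in names(x$agreement)) {
    a <- x$agreement[[nm]]
    cat(sprintf("  %-22s ICC(2,1) = %.3f, bias = %+.2f cm, LOA = [%.2f, %.2f]\n",
                nm, a$icc, a$bland_altman$bias_b,
                a$bland_altman$loa_low_c0, a$bland_altman$loa_high_c1))
  }
  invisible(x)
}

#' Write a session report to disk
#'
#' Emits `heights.csv` (per-repetition results), `report.csv` (wide
#' per-participant table), `agreement.json` (ICC, bias, LOA, mean R, TRR,
#' per-repetition scale evidence) and `qc_log.csv`.
#'
#' @param report a `session_report`.
#' @param dir output directory (created if missing).
#' @export
write_session_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$heights, file.path(dir, "heights.csv"), row.names = FALSE)
  utils::write.csv(report$table, file.path(dir, "report.csv"), row.names = FALSE)
  agr <- lapply(report$agreement, function(a)
    list(icc_2_1 = a$icc, bias_b = a$bland_altman$bias_b,
         sd_diff = a$bland_altman$sd_diff,
         loa = c(a$bland_altman$loa_low_c0, a$bland_altman$loa_high_c1),
         n_pairs = a$bland_altman$n_pairs))
  jsonlite::write_json(list(mean_R_mm_per_px = report$mean_R,
                            agreement = agr, trr = report$trr),
                       file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$qc))
    utils::write.csv(report$qc, file.path(dir, "qc_log.csv"), row.names = FALSE)
  invisible(dir)
}
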
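#' Jump height as maximum vertical toe displacement
#'
#' Height is measured directly from the kinematics as the maximum vertical
#' displacement of the fifth metatarsal (small toe) above its quiet-stance
#' baseline — more robust to jump strategy than centre-of-mass flight time.
#' The baseline is the median toe height over the leading `baseline_window`
#' seconds of the segment (the toe does not leave the ground until toe-off,
#' so the whole pre-flight window is usable baseline).
#'
#' @param toe_mm up-positive toe `sampled_series` in mm, denoised.
#' @param segment the repetition's `jump_segment`.
#' @param baseline_window quiet-stance window for the baseline, s.
#' @param method label for the result ("FP", "OMC", "MMC_RMM", "MMC_PTM").
#' @return a `jump_height_result`: `rep_id`, `method`, `height_cm`,
#'   `qc_flags` (inherited from the segment).
#' @export
toe_displacement_height <- function(toe_mm, segment, baseline_window = 0.5,
                                    method = "OMC") {
  stopifnot(inherits(toe_mm, "sampled_series"), inherits(segment, "jump_segment"))
  idx <- segment$start_index:segment$end_index
  x <- series_values(toe_mm, 1L)[idx]
  nb <- max(2L, round(baseline_window * toe_mm$rate))
  if (nb > length(x)) stop("baseline window longer than the segment; widen the segment")
  base_win <- x[seq_len(nb)]
  if (any(base_win == 0))
    stop("baseline window contains occlusion zero-runs; widen the window")
  baseline <- stats::median(base_win)
  height_cm <- (max(x) - baseline) / 10
  structure(list(rep_id = segment$rep_id, method = method,
                 height_cm = height_cm, qc_flags = segment$qc_flags),
            class = "jump_height_result")
}

#' @export
print.jump_height_result <- function(x, ...) {
  cat(sprintf("<jump_height_result> rep %d [%s]: %.2f cm%s\n", x$rep_id,
              x$method, x$height_cm,
              if (length(x$qc_flags)) paste0(" (", paste(x$qc_flags, collapse = ","), ")") else ""))
  invisible(x)
}

#' Per-participant mean jump heights
#'
#' Groups a long table of per-repetition heights by participant, task and
#' method and averages the unflagged repetitions, mirroring a session report
#' where each cell is the mean across repetitions. Repetitions flagged as
#' failures are excluded from the mean; a cell whose repetitions are all
#' excluded is marked "F" (failure), and cells excluded because their paired
#' rating is a failure can be pre-marked by the caller via `excluded`.
#'
#' @param results data.frame with columns `participant`, `task`, `method`,
#'   `rep_id`, `height_cm`, and logical `excluded`.
#' @return a wide data.frame: one row per participant x task, one column per
#'   method holding the mean height (NA when all reps excluded), plus a
#'   `marker_<method>` column ("" or "F") and `n_<method>` used counts.
#' @export
summarize_per_participant <- function(results) {
  stopifnot(all(c("participant", "task", "method", "rep_id", "height_cm",
                  "excluded") %in% names(results)))
  keys <- unique(results[, c("participant", "task")])
  keys <- keys[order(keys$participant, keys$task), , drop = FALSE]
  methods <- unique(results$method)
  out <- keys
  for (m in methods) {
    mv <- nv <- numeric(nrow(keys)); mk <- character(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      sel <- results$participant == keys$participant[i] &
        results$task == keys$task[i] & results$method == m
      used <- sel & !results$excluded
      nv[i] <- sum(used)
      mv[i] <- if (any(used)) mean(results$height_cm[used]) else NA_real_
      mk[i] <- if (any(sel) && !any(used)) "F" else ""
    }
    out[[m]] <- round(mv, 2)
    out[[paste0("n_", m)]] <- nv
    out[[paste0("marker_", m)]] <- mk
  }
  rownames(out) <- NULL
  out
}
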
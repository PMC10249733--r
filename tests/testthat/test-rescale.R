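test_that("reverse minmax restores any positive-affine pixel image of the reference", {
  set.seed(2)
  p <- sampled_series(100 + 500 * abs(sin(seq(0, 3, length.out = 200))), rate = 100,
                      unit = "mm")
  for (gain in c(0.3, 1, 7.5)) {
    q <- sampled_series(gain * series_values(p) - 42, rate = 100, unit = "px")
    out <- rescale_rmm(q, p)
    expect_lt(max(abs(series_values(out) - series_values(p))) /
                diff(range(series_values(p))), 1e-9)
  }
})

test_that("reverse minmax output range equals the reference range exactly", {
  q <- sampled_series(rnorm(100), rate = 30, unit = "px")
  p <- sampled_series(seq(100, 600, length.out = 100), rate = 30, unit = "mm")
  out <- rescale_rmm(q, p)
  expect_identical(range(series_values(out)), c(100, 600))
})

test_that("degenerate inputs to reverse minmax error clearly", {
  p <- sampled_series(seq(100, 600, length.out = 50), rate = 30)
  flatq <- sampled_series(rep(3, 50), rate = 30)
  expect_error(rescale_rmm(flatq, p), "degenerate pixel")
  q <- sampled_series(rnorm(50), rate = 30)
  flatp <- sampled_series(rep(300, 50), rate = 30)
  expect_error(rescale_rmm(q, flatp), "degenerate reference")
  expect_error(rescale_rmm(q, sampled_series(1:10, rate = 30)), "lengths differ")
})

# run the keypoint preprocessing used by the pipeline and return the
# 100 Hz up-positive hip with a whole-window segment
prep_hip <- function(rec, smooth = TRUE) {
  de <- remove_spikes_zscore(rec$mmc)
  hip_sm <- smooth_savgol(sampled_series(de$values[, "hip"], de$rate, unit = "px"))
  segs <- segment_repetitions(px_to_up(hip_sm), window_t = 1.5)
  sg <- segs[[1]]
  win <- series_window(sampled_series(de$values[, "hip"], de$rate, unit = "px"),
                       sg$start_index, sg$end_index)
  up <- resample_to_length(win, round(n_samples(win) * 100 / 30))
  if (smooth) up <- smooth_savgol(up)
  hip <- px_to_up(up)
  list(hip = hip, seg = jump_segment(which.max(series_values(hip)), 1L,
                                     n_samples(hip), 1L))
}

test_that("free-fall calibration recovers the true scale on noise-free data", {
  rec <- simulate_recording(noise_free_spec(true_height = 20))
  pr <- prep_hip(rec)
  est <- estimate_ptm_scale(pr$hip, pr$seg)
  expect_equal(est$source, "fitted")
  expect_lt(abs(est$R - 3.43) / 3.43, 0.02)
  expect_gt(est$free_fall_T, 0)
  # Eq-consistency of the stored evidence: R = 500 T^2 g / drop
  expect_equal(est$R, 500 * est$free_fall_T^2 * 9.81 / est$pixel_drop,
               tolerance = 1e-9)
})

test_that("flat hip series is not estimable", {
  flat <- sampled_series(rep(100, 200), rate = 100, unit = "px")
  sg <- jump_segment(100L, 1L, 200L, 1L)
  expect_error(estimate_ptm_scale(flat, sg), class = "cmjump_not_estimable")
})

test_that("calibration stays within 10% under 1 px keypoint noise", {
  errs <- vapply(1:20, function(s) {
    rec <- simulate_recording(jump_spec(true_height = 20, n_reps = 1,
                                        pixel_noise_sd = 1, spike_prob = 0,
                                        seed = s))
    pr <- prep_hip(rec)
    est <- estimate_ptm_scale(pr$hip, pr$seg)
    abs(est$R - 3.43) / 3.43
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("applying a scale multiplies every sample", {
  x <- sampled_series(c(1, 2, 3), rate = 30, unit = "px")
  expect_equal(series_values(apply_scale(x, 1)), c(1, 2, 3))
  expect_equal(series_values(apply_scale(x, 2)), c(2, 4, 6))
  expect_equal(apply_scale(x, scale_estimate(2))$unit, "mm")
})

test_that("scaling noise-free keypoints reproduces the metric trajectory", {
  sp <- noise_free_spec(true_height = 20)
  rec <- simulate_recording(sp)
  mo30 <- simulate_motion(sp, rate = 30)
  hip_up <- px_to_up(sampled_series(rec$mmc$values[, "hip"], 30, unit = "px"))
  scaled <- series_values(apply_scale(hip_up, sp$scale_R_true))
  truth <- mo30$hip_height * 1000
  # equal up to the constant image-origin offset
  expect_lt(max(abs((scaled - mean(scaled)) - (truth - mean(truth)))) /
              diff(range(truth)), 1e-6)
})

test_that("cohort mean fallback averages fitted estimates", {
  ests <- list(scale_estimate(3), scale_estimate(4))
  fb <- cohort_mean_fallback(ests)
  expect_equal(fb$R, 3.5)
  expect_equal(fb$source, "cohort_mean_fallback")
  single <- cohort_mean_fallback(list(scale_estimate(3.1)))
  expect_equal(single$R, 3.1)
  expect_equal(single$source, "cohort_mean_fallback")
  expect_error(cohort_mean_fallback(list()), "no fitted")
  # already-fallback estimates are not pooled again
  expect_error(cohort_mean_fallback(list(fb)), "no fitted")
})
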
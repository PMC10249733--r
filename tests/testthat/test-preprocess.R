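test_that("spike removal leaves clean series untouched", {
  ramp <- sampled_series(seq(0, 10, length.out = 100), rate = 30)
  out <- remove_spikes_zscore(ramp)
  expect_equal(out$values, ramp$values)
  const <- sampled_series(rep(5, 50), rate = 30)
  expect_equal(remove_spikes_zscore(const)$values, const$values)
})

test_that("an inserted spike is recovered to within the noise floor", {
  sd_ref <- 0.05
  t <- seq(0, 5, by = 1 / 30)
  clean <- sin(2 * pi * 0.4 * t)
  spiked <- clean
  spiked[60] <- spiked[60] + 50 * sd_ref
  out <- remove_spikes_zscore(sampled_series(spiked, rate = 30), z_thresh = 3)
  expect_lt(max(abs(series_values(out) - clean)), sd_ref)
  expect_true(60 %in% attr(out, "spike_idx")[[1]])
})

test_that("genuine fast motion is not mistaken for spikes", {
  rec <- simulate_recording(noise_free_spec(true_height = 25))
  out <- remove_spikes_zscore(rec$mmc)
  expect_length(attr(out, "spike_idx")[[1]], 0L)
  expect_equal(out$values, rec$mmc$values)
})

test_that("occlusion dropouts are repaired by interpolation", {
  x <- 900 + sin(seq(0, 4, by = 0.01))
  x[150:160] <- 0
  rep <- repair_dropouts(sampled_series(x, rate = 100, unit = "mm"))
  expect_false(any(series_values(rep) == 0))
  truth <- 900 + sin(seq(0, 4, by = 0.01))
  expect_lt(max(abs(series_values(rep) - truth)), 0.01)
})

test_that("Savitzky-Golay reproduces quadratics exactly and smooths noise", {
  t <- seq(0, 3, by = 0.01)
  quad <- 2 + 3 * t - 4 * t^2
  out <- smooth_savgol(sampled_series(quad, rate = 100))
  expect_equal(series_values(out), quad, tolerance = 1e-10)
  const <- smooth_savgol(sampled_series(rep(1.5, 50), rate = 100))
  expect_equal(series_values(const), rep(1.5, 50), tolerance = 1e-12)
  set.seed(11)
  noisy <- quad + rnorm(length(t), 0, 1)
  sm <- smooth_savgol(sampled_series(noisy, rate = 100))
  expect_lt(sd(series_values(sm) - quad), 0.5)
  expect_error(smooth_savgol(sampled_series(1:10, rate = 100)), "window")
})

test_that("segmentation finds one window per repetition at the true apexes", {
  sp <- noise_free_spec(true_height = 20, n_reps = 3)
  rec <- simulate_recording(sp)
  hip <- sampled_series(series_values(rec$omc, "hip"), rate = 100, unit = "mm")
  segs <- segment_repetitions(smooth_savgol(hip), window_t = 1.5)
  expect_length(segs, 3L)
  peaks <- vapply(segs, `[[`, integer(1), "peak_index")
  truth <- round(rec$truth$t_apex * 100) + 1
  expect_true(all(abs(peaks - truth) <= 2))
  expect_equal(vapply(segs, `[[`, integer(1), "rep_id"), 1:3)
})

test_that("segment count is stable across seeds under pixel noise", {
  for (s in 1:20) {
    sp <- jump_spec(true_height = 20, n_reps = 3, pixel_noise_sd = 2,
                    spike_prob = 0, seed = s)
    rec <- simulate_recording(sp)
    de <- remove_spikes_zscore(rec$mmc)
    hip <- smooth_savgol(sampled_series(de$values[, "hip"], de$rate, unit = "px"))
    segs <- segment_repetitions(px_to_up(hip), window_t = 1.5)
    expect_length(segs, 3L)
  }
})

test_that("flat series segment to nothing", {
  flat <- sampled_series(rep(1, 500), rate = 100)
  expect_length(segment_repetitions(flat), 0L)
})

test_that("of two close peaks only the more prominent is kept", {
  t <- seq(0, 10, by = 0.01)
  x <- 2 * exp(-(t - 4)^2 / 0.05) + exp(-(t - 5)^2 / 0.05)  # 1 s apart
  segs <- segment_repetitions(sampled_series(x, rate = 100), window_t = 1.5)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$peak_index, which.max(x))
})

test_that("windows clipped by the series bounds are flagged", {
  t <- seq(0, 3, by = 0.01)
  x <- exp(-(t - 1)^2 / 0.05)
  segs <- segment_repetitions(sampled_series(x, rate = 100), window_t = 1.5)
  expect_true("clipped_window" %in% segs[[1]]$qc_flags)
})

test_that("QC flags fire on failure fixtures and pass clean reps", {
  sp <- noise_free_spec(true_height = 20)
  rec <- simulate_recording(sp)
  hip <- px_to_up(sampled_series(rec$mmc$values[, "hip"], 30, unit = "px"))
  segs <- segment_repetitions(smooth_savgol(hip), window_t = 1.5)
  clean <- flag_uncharacteristic(segs[[1]], hip,
                                 confidence = rec$mmc$confidence[, "hip"])
  expect_false(any(c("uncharacteristic", "low_confidence") %in% clean$qc_flags))

  low <- flag_uncharacteristic(segs[[1]], hip,
                               confidence = rep(0.1, n_samples(hip)))
  expect_true("low_confidence" %in% low$qc_flags)

  bad <- simulate_recording(jump_spec(true_height = 20, seed = 5,
                                      failure_mode = "uncharacteristic"))
  hip_b <- px_to_up(smooth_savgol(
    sampled_series(remove_spikes_zscore(bad$mmc)$values[, "hip"], 30, unit = "px")))
  segs_b <- segment_repetitions(hip_b, window_t = 1.5)
  expect_gt(length(segs_b), 0L)
  flags <- unlist(lapply(segs_b, function(s)
    flag_uncharacteristic(s, hip_b)$qc_flags))
  expect_true("uncharacteristic" %in% flags)
})

test_that("Fourier resampling is exact for band-limited inputs", {
  # identity at the same length
  x <- sampled_series(sin(2 * pi * 3 * seq(0, 1, by = 1 / 30)[1:30]), rate = 30)
  expect_equal(resample_to_length(x, 30)$values, x$values)
  # a periodic tone resampled 30 -> 100 Hz matches the analytic sinusoid
  t30 <- (0:29) / 30
  tone <- sampled_series(sin(2 * pi * 4 * t30), rate = 30)
  up <- resample_to_length(tone, 100)
  t100 <- (0:99) / 100
  expect_equal(up$rate, 100)
  expect_lt(max(abs(series_values(up) - sin(2 * pi * 4 * t100))), 1e-6)
  # constants stay constant, mean is preserved
  const <- resample_to_length(sampled_series(rep(2.5, 40), rate = 30), 111)
  expect_equal(series_values(const), rep(2.5, 111), tolerance = 1e-12)
  expect_equal(mean(series_values(up)), mean(series_values(tone)), tolerance = 1e-12)
})

test_that("upsampling then decimating recovers the original samples", {
  set.seed(3)
  # band-limited signal: few low-frequency Fourier components on 30 samples
  t30 <- (0:29) / 30
  x <- 0.7 * sin(2 * pi * 2 * t30) + 0.3 * cos(2 * pi * 5 * t30)
  up <- resample_to_length(sampled_series(x, rate = 30), 90)
  back <- series_values(up)[seq(1, 90, by = 3)]
  expect_lt(max(abs(back - x)) / diff(range(x)), 1e-6)
})

test_that("downsampling requests are refused", {
  x <- sampled_series(rnorm(50), rate = 100)
  expect_error(resample_to_length(x, 40), "upsamples only")
})
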
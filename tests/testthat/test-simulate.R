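test_that("implied flight duration matches the ballistic oracle", {
  # 19.62 cm corresponds to a 0.400 s flight
  sp <- noise_free_spec(true_height = 19.62)
  mo <- simulate_motion(sp)
  Tf <- mo$reps$t_land - mo$reps$t_toe_off
  expect_equal(Tf, 0.400, tolerance = 1e-9)
  expect_equal(ballistic_apex_cm(Tf), 19.62, tolerance = 1e-6)
  # the sampled phase labels agree with the analytic interval
  expect_equal(sum(mo$phase == "flight"), round(Tf * mo$rate), tolerance = 1)
})

test_that("zero-height spec yields a countermovement with no flight", {
  mo <- simulate_motion(noise_free_spec(true_height = 0))
  expect_setequal(as.character(unique(mo$phase)),
                  c("stance", "countermovement", "propulsion"))
  expect_true(all(mo$vertical_force > 0))
})

test_that("n_reps flight phases are separated by at least the rest period", {
  sp <- noise_free_spec(true_height = 25, n_reps = 3, rest_between_reps = 1.5)
  mo <- simulate_motion(sp)
  expect_equal(nrow(mo$reps), 3L)
  gaps <- mo$reps$t_toe_off[-1] - mo$reps$t_land[-3]
  expect_true(all(gaps >= sp$rest_between_reps))
})

test_that("spec validation rejects bad heights and masses", {
  expect_error(jump_spec(true_height = -1), "non-negative")
  expect_error(jump_spec(body_mass = 0), "positive")
  expect_error(jump_spec(spike_prob = 1.5))
})

test_that("identical spec and seed give bit-identical recordings", {
  sp <- jump_spec(true_height = 22, seed = 11)
  a <- simulate_recording(sp)
  b <- simulate_recording(sp)
  expect_identical(a$force$values, b$force$values)
  expect_identical(a$omc$values, b$omc$values)
  expect_identical(a$mmc$values, b$mmc$values)
  expect_identical(a$mmc$confidence, b$mmc$confidence)
})

test_that("noise-free force trace is exactly zero in flight and bodyweight in stance", {
  sp <- noise_free_spec(true_height = 20, body_mass = 70)
  rec <- simulate_recording(sp)
  mo <- simulate_motion(sp)
  f <- series_values(rec$force)
  fl <- mo$phase == "flight"
  expect_true(all(f[fl] == 0))
  stance_mean <- mean(f[seq_len(round(0.5 * rec$force$rate))])
  expect_equal(stance_mean, 70 * 9.81, tolerance = 0.01)
})

test_that("force noise on the unloaded plate has the configured sd", {
  sp <- jump_spec(true_height = 25, force_noise_sd = 2, seed = 3)
  rec <- simulate_recording(sp)
  mo <- rec$motion
  fl <- which(mo$phase == "flight")
  expect_gte(length(fl), 400)
  expect_equal(sd(series_values(rec$force)[fl]), 2, tolerance = 0.2)
})

test_that("noise-free marker rendering reproduces the true height exactly", {
  sp <- noise_free_spec(true_height = 20)
  rec <- simulate_recording(sp)
  toe <- series_values(rec$omc, "toe")
  baseline <- median(toe[1:50])
  expect_equal(max(toe) - baseline, 200, tolerance = 1e-9)
})

test_that("marker dropout injects zero-valued runs", {
  sp <- jump_spec(true_height = 20, seed = 9)
  rec <- simulate_recording(sp, dropout = TRUE)
  expect_true(any(rec$omc$values == 0))
})

test_that("noise-free keypoints are an exact affine image of the metric trajectory", {
  sp <- noise_free_spec(true_height = 20)
  rec <- simulate_recording(sp)
  mo30 <- simulate_motion(sp, rate = 30)
  hip_mm <- (600 - series_values(rec$mmc, "hip")) * sp$scale_R_true
  expect_equal(hip_mm, mo30$hip_height * 1000, tolerance = 1e-9)
  expect_true(all(rec$mmc$confidence == 0.9))
})

test_that("spike frames are seeded, isolated and reproducible", {
  sp <- jump_spec(true_height = 20, spike_prob = 0.02, pixel_noise_sd = 1, seed = 21)
  a <- simulate_recording(sp)
  b <- simulate_recording(sp)
  spikes <- which(a$mmc$confidence < 0.9)
  expect_identical(spikes, which(b$mmc$confidence < 0.9))
  n <- 2 * n_samples(a$mmc)
  # binomial count around n * p
  expect_gt(length(spikes), 0)
  expect_lt(length(spikes), n * 0.02 + 4 * sqrt(n * 0.02))
})

test_that("the three modalities agree on apex timing within one coarse sample", {
  sp <- noise_free_spec(true_height = 20)
  rec <- simulate_recording(sp)
  t_omc <- series_time(rec$omc)[which.max(series_values(rec$omc, "hip"))]
  t_mmc <- series_time(rec$mmc)[which.min(series_values(rec$mmc, "hip"))] # image-down
  t_true <- rec$truth$t_apex
  expect_lt(abs(t_omc - t_true), 1 / 30 + 1e-9)
  expect_lt(abs(t_mmc - t_true), 1 / 30 + 1e-9)
})

test_that("per-rep heights drive distinct flights", {
  sp <- noise_free_spec(true_height = 20, n_reps = 3)
  sp$rep_heights <- c(15, 20, 25)
  mo <- simulate_motion(sp)
  Tf <- mo$reps$t_land - mo$reps$t_toe_off
  expect_equal(Tf, flight_time_from_height(c(15, 20, 25)), tolerance = 1e-9)
})
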
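test_that("identical raters give perfect agreement", {
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_2_1(m), 1)
})

test_that("the mean-squares estimator matches the ANOVA oracle", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(rnorm(40, mean = 10, sd = 2), 10, 4)
    expect_equal(icc_2_1(m), icc_anova_oracle(m), tolerance = 1e-10)
  }
})

test_that("absolute agreement penalizes a systematic rater offset", {
  set.seed(5)
  subj <- rnorm(30, 20, 1)
  base <- icc_2_1(cbind(subj, subj + rnorm(30, 0, 0.1)))
  offset <- icc_2_1(cbind(subj, subj + 5 + rnorm(30, 0, 0.1)))
  expect_lt(offset, base)
})

test_that("ICC is invariant to common shifts and positive scalings", {
  set.seed(8)
  m <- matrix(rnorm(24, 15, 3), 8, 3)
  expect_equal(icc_2_1(m + 100), icc_2_1(m), tolerance = 1e-12)
  expect_equal(icc_2_1(m * 3.7), icc_2_1(m), tolerance = 1e-12)
})

test_that("constant matrices are flagged undefined", {
  out <- icc_2_1(matrix(5, 4, 3))
  expect_true(is.na(out))
  expect_match(attr(out, "diagnostic"), "zero total variance")
})

test_that("rows with missing cells are dropped listwise", {
  m <- cbind(c(1, 5, 9, NA), c(1.1, 5.2, 8.9, 2))
  expect_equal(icc_2_1(m), icc_2_1(m[1:3, ]))
  expect_error(icc_2_1(cbind(c(1, NA), c(2, NA))), "at least 2 subjects")
})

test_that("test-retest reliability follows the variance ratio", {
  # identical repetitions: perfect reliability
  reps <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  expect_equal(icc_test_retest(reps), 1)
  # between-subject sd 8, rep jitter 0.5: expected ICC ~ 64/64.25
  med <- median(vapply(1:20, function(s) {
    set.seed(s)
    subj <- rnorm(16, 20, 8)
    icc_test_retest(subj + matrix(rnorm(48, 0, 0.5), 16, 3))
  }, numeric(1)))
  expect_gt(med, 0.95)
  # jitter equal to between-subject sd: expected ICC ~ 0.5
  med2 <- median(vapply(1:20, function(s) {
    set.seed(s)
    subj <- rnorm(16, 20, 8)
    icc_test_retest(subj + matrix(rnorm(48, 0, 8), 16, 3))
  }, numeric(1)))
  expect_equal(med2, 0.5, tolerance = 0.15)
})

test_that("Bland-Altman handles exact agreement and exact offsets", {
  x <- c(10, 15, 20, 25)
  r0 <- bland_altman(x, x)
  expect_equal(r0$bias_b, 0)
  expect_equal(c(r0$loa_low_c0, r0$loa_high_c1), c(0, 0))
  r2 <- bland_altman(x + 2, x)
  expect_equal(r2$bias_b, 2)
  expect_equal(r2$sd_diff, 0)
  expect_equal(c(r2$loa_low_c0, r2$loa_high_c1), c(2, 2))
})

test_that("LOA width is exactly 2 * 1.96 * sd of the differences", {
  set.seed(4)
  m <- rnorm(50, 20, 5); t <- m + rnorm(50)
  r <- bland_altman(m, t)
  expect_equal(r$loa_high_c1 - r$loa_low_c0, 2 * 1.96 * sd(m - t), tolerance = 1e-12)
  expect_true(r$loa_low_c0 <= r$bias_b && r$bias_b <= r$loa_high_c1)
})

test_that("about 95% of normal differences fall inside the LOA", {
  set.seed(99)
  truth <- rnorm(1000, 20, 5)
  method <- truth + rnorm(1000)
  r <- bland_altman(method, truth)
  inside <- mean(r$diffs >= r$loa_low_c0 & r$diffs <= r$loa_high_c1)
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
})

test_that("incomplete pairs are dropped and tiny inputs error", {
  r <- bland_altman(c(1, 2, NA, 4), c(1, 2, 3, NA))
  expect_equal(r$n_pairs, 2L)
  expect_error(bland_altman(1, 1))
  expect_error(bland_altman(c(1, NA), c(1, 2)), "at least 2")
})
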
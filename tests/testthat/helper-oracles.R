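# Independent oracles used to freeze expected values.

# Apex height (cm) of a ballistic trajectory with flight time Tf, by numeric
# integration: take-off speed g*Tf/2 (apex at mid-flight by symmetry),
# velocity-Verlet steps (exact for uniform gravity), apex refined by a
# three-point parabola through the grid maximum.
ballistic_apex_cm <- function(Tf, g = 9.81, dt = 1e-4) {
  v0 <- g * Tf / 2
  t <- seq(0, Tf, by = dt)
  y <- numeric(length(t))
  v <- v0
  for (i in seq_along(t)[-1]) {
    y[i] <- y[i - 1] + v * dt - 0.5 * g * dt^2
    v <- v - g * dt
  }
  i <- which.max(y)
  if (i > 1 && i < length(y)) {
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    apex <- if (abs(denom) > 0) y2 - (y3 - y1)^2 / (8 * denom) else y2
  } else apex <- y[i]
  100 * apex
}

# ICC(2,1) by an independent route: two-way ANOVA decomposition via
# stats::aov, mean squares read from the ANOVA table.
icc_anova_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  MSR <- tab["subj", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# a quiet noise-free spec, shared by exactness tests
noise_free_spec <- function(true_height = 20, n_reps = 1, ...) {
  jump_spec(true_height = true_height, n_reps = n_reps,
            pixel_noise_sd = 0, marker_noise_sd = 0, force_noise_sd = 0,
            spike_prob = 0, ...)
}
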
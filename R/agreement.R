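#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater/measurement
#' (McGraw & Wong convention). Computed from the two-way ANOVA mean squares
#' of a subjects x raters matrix:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the row (subject), column (rater) and residual
#' mean squares. Absolute agreement penalises systematic offsets between
#' raters, unlike consistency-type ICCs. Rows containing missing values are
#' dropped listwise.
#'
#' @param ratings numeric matrix, n subjects x k raters (n >= 2, k >= 2).
#' @return the ICC point estimate; `NA` (with a `diagnostic` attribute) when
#'   the total variance is zero.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  ratings <- ratings[stats::complete.cases(ratings), , drop = FALSE]
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters after listwise deletion")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm_ <- colMeans(ratings)
  SSR <- k * sum((rm_ - grand)^2)
  SSC <- n * sum((cm_ - grand)^2)
  SSE <- sum((ratings - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2)
  if (SSR + SSC + SSE <= .Machine$double.eps * abs(grand + 1) * n * k) {
    out <- NA_real_
    attr(out, "diagnostic") <- "zero total variance: ICC undefined"
    return(out)
  }
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

#' Intra-session test-retest reliability
#'
#' ICC(2,1) applied with repetitions as the "raters": participants are the
#' subjects and each of the k repetitions of one method is a rating, giving
#' the within-method test-retest reliability across repetitions.
#'
#' @param reps numeric matrix, participants x repetitions, for one method.
#' @return the test-retest ICC point estimate.
#' @export
icc_test_retest <- function(reps) icc_2_1(reps)

#' Bland-Altman agreement analysis
#'
#' Bias `b` is the mean of the pairwise differences (oriented
#' `method - truth`); the limits of agreement are `c0 = b - 1.96 SD` and
#' `c1 = b + 1.96 SD`, where SD is the sample standard deviation (n - 1
#' denominator) of the differences. About 95% of differences are expected
#' to fall inside \[c0, c1\]. Pairs with a missing member are dropped
#' listwise.
#'
#' @param method numeric vector of candidate-method measurements.
#' @param truth numeric vector of ground-truth measurements (same length).
#' @return an `agreement_report`: `bias_b`, `loa_low_c0`, `loa_high_c1`,
#'   `sd_diff`, `n_pairs`, and per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(method, truth) {
  stopifnot(length(method) == length(truth))
  ok <- stats::complete.cases(method, truth)
  method <- method[ok]; truth <- truth[ok]
  if (length(method) < 2) stop("need at least 2 complete pairs")
  diffs <- method - truth
  b <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(bias_b = b, sd_diff = s,
                 loa_low_c0 = b - 1.96 * s, loa_high_c1 = b + 1.96 * s,
                 n_pairs = length(diffs),
                 means = (method + truth) / 2, diffs = diffs),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d: bias = %.2f, LOA = [%.2f, %.2f]\n",
              x$n_pairs, x$bias_b, x$loa_low_c0, x$loa_high_c1))
  invisible(x)
}

#' Bland-Altman scatter data as a data.frame
#' @param report an `agreement_report`.
#' @export
bland_altman_data <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  data.frame(mean = report$means, diff = report$diffs)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair means against differences with the bias and limits of
#' agreement as horizontal lines. Requires ggplot2.
#'
#' @param report an `agreement_report`.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(report, title = "Bland-Altman") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- bland_altman_data(report)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = report$bias_b, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(report$loa_low_c0, report$loa_high_c1),
                        linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of methods (cm)",
                  y = "Difference (cm)") +
    ggplot2::theme_minimal()
}
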
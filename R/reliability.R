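#' One-way random-effects intraclass correlation for test-retest data
#'
#' Single-measure ICC from the one-way ANOVA decomposition of paired
#' (test, retest) scores: `ICC = (MSB - MSW) / (MSB + (k-1) MSW)` with
#' `k = 2` replicates per subject.  The two waves are treated as
#' interchangeable within subject, which matches the subject-variance
#' vs. measurement-error reading of reliability.  The 95% confidence
#' interval is obtained from the F pivot `F0 = MSB/MSW` with
#' `FL = F0 / qf(1 - alpha/2, n-1, n)` and
#' `FU = F0 * qf(1 - alpha/2, n, n-1)`, each bound mapped through
#' `(F - 1) / (F + k - 1)`.
#'
#' Negative estimates (within-subject scatter exceeding between-subject
#' scatter) are reported as computed and banded as "poor".
#'
#' @param x,y Numeric vectors of test and retest scores, aligned by
#'   subject; incomplete pairs must be dropped upstream.
#' @param alpha Significance level for the CI (default 0.05).
#' @return Object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `band`, `ms_between`, `ms_within`, `f`, `n`.
#' @seealso [landis_koch_band()]
#' @export
#' @examples
#' set.seed(1)
#' s <- rnorm(50); icc_oneway(s + rnorm(50, sd = 0.5), s + rnorm(50, sd = 0.5))
icc_oneway <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("icc_oneway: need at least 3 complete pairs", call. = FALSE)
  k <- 2
  subj_mean <- (x + y) / 2
  grand <- mean(c(x, y))
  ssb <- k * sum((subj_mean - grand)^2)
  ssw <- sum((x - subj_mean)^2 + (y - subj_mean)^2)
  if (ssb + ssw <= 0) stop("icc_oneway: degenerate sample (zero total variance)",
                           call. = FALSE)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw == 0 && msb == 0) stop("icc_oneway: degenerate sample", call. = FALSE)
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f0 <- msb / msw
  fl <- f0 / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f0 * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2],
         band = landis_koch_band(icc), ms_between = msb, ms_within = msw,
         f = f0, n = n, alpha = alpha),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (one-way, single measure) = %.3f, %d%% CI (%.3f, %.3f) [%s], n = %d\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$band,
              x$n))
  invisible(x)
}

#' Landis-Koch agreement band
#'
#' Conventional labels for agreement coefficients: poor up to 0.2, fair
#' (0.2, 0.4], moderate (0.4, 0.6], substantial (0.6, 0.8], almost
#' perfect (0.8, 1].  Intervals are right-closed; estimates at or below
#' zero are "poor" (the coefficient's floor is theoretically 0).
#'
#' @param icc Numeric vector of coefficients, each at most 1.
#' @return Character vector of band labels.
#' @export
#' @examples
#' landis_koch_band(c(0.42, 0.28, 1.0))
landis_koch_band <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) {
    stop("landis_koch_band: coefficient exceeds 1", call. = FALSE)
  }
  labels <- c("poor", "fair", "moderate", "substantial", "almost perfect")
  # left.open makes each band right-closed: 0.4 is still "fair"
  idx <- findInterval(pmin(icc, 1), c(0.2, 0.4, 0.6, 0.8),
                      left.open = TRUE) + 1L
  labels[idx]
}

#' Paired t test with Dunlap-corrected effect size
#'
#' Standard paired t test plus Cohen's d corrected for paired designs:
#' `d = t * sqrt(2 (1 - r) / n)`, where `r` is the test-retest Pearson
#' correlation.  The correction prevents the within-subject correlation
#' from inflating the apparent effect.  By convention the effect size is
#' displayed only when the test is significant at `alpha` (large-sample
#' surveys make tiny mean shifts "significant"); the estimate itself is
#' always stored.
#'
#' @inheritParams icc_oneway
#' @return Object of class `paired_test_result`: `t`, `df`, `p`, `d`,
#'   `significant`, `mean_diff`, `r`, `n`, `mean_x`, `sd_x`, `mean_y`,
#'   `sd_y`.
#' @export
paired_t_dunlap <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("paired_t_dunlap: need at least 3 complete pairs",
                   call. = FALSE)
  d_i <- x - y
  if (stats::sd(d_i) == 0) {
    stop("paired_t_dunlap: zero variance of differences, t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  r <- stats::cor(x, y)
  d <- unname(tt$statistic) * sqrt(2 * (1 - r) / n)
  structure(
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, d = d, significant = tt$p.value < alpha,
         mean_diff = mean(d_i), r = r, n = n,
         mean_x = mean(x), sd_x = stats::sd(x),
         mean_y = mean(y), sd_y = stats::sd(y), alpha = alpha),
    class = "paired_test_result"
  )
}

#' @export
print.paired_test_result <- function(x, verbose = FALSE, ...) {
  d_txt <- if (x$significant || verbose) sprintf("d = %.2f", x$d) else "d not reported (n.s.)"
  cat(sprintf("paired t(%d) = %.2f, p = %.3g, %s\n", x$df, x$t, x$p, d_txt))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' `z = atanh(r)` is approximately normal with standard error
#' `1/sqrt(n - 3)`; the CI is `tanh(z +/- z_(1-alpha/2)/sqrt(n-3))`,
#' asymmetric about `r` except at zero.
#'
#' @param x,y Numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `corr_result`: `r`, `ci_low`, `ci_high`, `n`,
#'   `method = "pearson"`.
#' @export
pearson_fisher_ci <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("pearson_fisher_ci: need at least 4 complete pairs",
                   call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_fisher_ci: constant input, correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  structure(
    list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw), n = n,
         method = "pearson", alpha = alpha),
    class = "corr_result"
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks, with average ranks for ties.
#'
#' @inheritParams pearson_fisher_ci
#' @return Object of class `corr_result` with `r` (rho), `n`,
#'   `method = "spearman"` (no CI).
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_rho: need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("spearman_rho: constant ranks, correlation undefined", call. = FALSE)
  }
  structure(
    list(r = stats::cor(rx, ry), ci_low = NA_real_, ci_high = NA_real_,
         n = n, method = "spearman", alpha = NA_real_),
    class = "corr_result"
  )
}

#' @export
print.corr_result <- function(x, ...) {
  if (is.na(x$ci_low)) {
    cat(sprintf("%s r = %.3f, n = %d\n", x$method, x$r, x$n))
  } else {
    cat(sprintf("%s r = %.3f, %d%% CI (%.3f, %.3f), n = %d\n",
                x$method, x$r, round(100 * (1 - x$alpha)), x$ci_low,
                x$ci_high, x$n))
  }
  invisible(x)
}
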
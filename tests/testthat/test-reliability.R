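test_that("icc_oneway matches the classical ANOVA decomposition", {
  # identity with between-subject spread: perfect reliability
  x <- c(1, 2, 3, 4, 5, 6)
  r <- icc_oneway(x, x)
  expect_equal(r$icc, 1)
  expect_equal(r$band, "almost perfect")

  set.seed(101)
  for (rep in 1:5) {
    x <- rnorm(12); y <- 0.6 * x + rnorm(12, sd = 0.8)
    r <- icc_oneway(x, y)
    expect_equal(r$icc, oracle_icc_aov(x, y), tolerance = 1e-12)
  }
  expect_error(icc_oneway(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(icc_oneway(1:2, 2:3), "at least 3")
})

test_that("icc_oneway recovers the variance-ratio ground truth", {
  set.seed(202)
  n <- 1000
  subj <- rnorm(n, sd = 1)
  r <- icc_oneway(subj + rnorm(n, sd = 1), subj + rnorm(n, sd = 1))
  expect_lt(abs(r$icc - 0.5), 0.05)
  expect_lt(r$ci_low, r$icc)
  expect_gt(r$ci_high, r$icc)
})

test_that("Landis-Koch bands are exhaustive, exclusive, and right-closed", {
  expect_equal(landis_koch_band(0.42), "moderate")
  expect_equal(landis_koch_band(0.28), "fair")
  expect_equal(landis_koch_band(1.0), "almost perfect")
  expect_equal(landis_koch_band(c(-0.3, 0, 0.2, 0.4, 0.6, 0.8)),
               c("poor", "poor", "poor", "fair", "moderate", "substantial"))
  grid <- seq(-1, 1, by = 0.001)
  bands <- landis_koch_band(grid)
  expect_true(all(bands %in% c("poor", "fair", "moderate", "substantial",
                               "almost perfect")))
  expect_false(is.unsorted(match(bands, c("poor", "fair", "moderate",
                                          "substantial", "almost perfect"))))
  expect_error(landis_koch_band(1.2), "exceeds 1")
})

test_that("paired t carries the Dunlap-corrected effect size", {
  set.seed(7)
  x <- rnorm(10); y <- 0.8 * x + rnorm(10, sd = 0.5) + 0.4
  res <- paired_t_dunlap(x, y)
  # recompute everything from first principles
  d_i <- x - y
  t_hand <- mean(d_i) / (sd(d_i) / sqrt(10))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$d, t_hand * sqrt(2 * (1 - cor(x, y)) / 10),
               tolerance = 1e-12)
  expect_equal(sign(res$d), sign(res$mean_diff))
  expect_equal(res$df, 9)

  # constant shift: large |t|, d signed like the shift
  shift <- paired_t_dunlap(x, x - 0.5 + rnorm(10, sd = 1e-3))
  expect_gt(shift$t, 10)
  expect_gt(shift$d, 0)
  expect_error(paired_t_dunlap(x, x), "zero variance")
})

test_that("Fisher-z CIs have the closed form and shrink with n", {
  expect_equal(atanh(0.5), 0.5 * log(3))
  set.seed(9)
  x <- rnorm(103)
  y <- 0.5 * x + rnorm(103, sd = sqrt(1 - 0.25))
  res <- pearson_fisher_ci(x, y)
  r <- cor(x, y)
  expect_equal(res$ci_low, tanh(atanh(r) - qnorm(0.975) / sqrt(100)),
               tolerance = 1e-12)
  expect_equal(res$ci_high, tanh(atanh(r) + qnorm(0.975) / sqrt(100)),
               tolerance = 1e-12)
  # symmetric about zero when r = 0
  x0 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  y0 <- c(1, 1, 2, 2, 2, 2, 1, 1)
  res0 <- pearson_fisher_ci(x0, y0)
  expect_equal(res0$r, 0)
  expect_equal(res0$ci_low, -res0$ci_high)
  # width decreases monotonically in n for fixed r
  widths <- vapply(c(10, 20, 50, 200), function(n) {
    z <- atanh(0.5)
    hw <- qnorm(0.975) / sqrt(n - 3)
    tanh(z + hw) - tanh(z - hw)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(pearson_fisher_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("spearman_rho is the rank Pearson with average ranks for ties", {
  expect_equal(spearman_rho(1:13, (1:13)^2)$r, 1)
  expect_equal(spearman_rho(1:13, rev(1:13))$r, -1)
  # one adjacent swap in a 13-item ranking: classical formula 1 - 6*sum(d^2)/(n(n^2-1))
  y <- 1:13; y[c(4, 5)] <- y[c(5, 4)]
  d2 <- sum((1:13 - y)^2)
  expect_equal(spearman_rho(1:13, y)$r, 1 - 6 * d2 / (13 * (13^2 - 1)))
  # ties handled by average ranks: agrees with cor(..., method = "spearman")
  set.seed(5)
  a <- sample(1:5, 30, replace = TRUE); b <- sample(1:5, 30, replace = TRUE)
  expect_equal(spearman_rho(a, b)$r, cor(a, b, method = "spearman"))
  expect_error(spearman_rho(rep(2, 5), 1:5), "constant")
})

test_that("group difference tests report the right effect sizes", {
  # identical group means: f = 0
  v <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(anova_cohens_f(v, g)$cohens_f, 0)
  # proportional rows: V = 0
  expect_equal(chisq_cramers_v(matrix(c(40, 10, 40, 10), 2))$cramers_v, 0)
  # fixed 4x5 table against a hand chi-square
  set.seed(13)
  tab <- matrix(rpois(20, 12) + 1, 4, 5)
  hand <- 0
  for (i in 1:4) for (j in 1:5) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
    hand <- hand + (tab[i, j] - e)^2 / e
  }
  res <- chisq_cramers_v(tab)
  expect_equal(res$chi2, hand, tolerance = 1e-12)
  expect_equal(res$cramers_v, sqrt(hand / (sum(tab) * 3)), tolerance = 1e-12)
  # Hedges' g small-sample correction
  set.seed(14)
  x <- rnorm(12, 1); y <- rnorm(15)
  sp <- sqrt((11 * var(x) + 14 * var(y)) / 25)
  expect_equal(hedges_g(x, y)$hedges_g,
               (1 - 3 / (4 * 27 - 9)) * (mean(x) - mean(y)) / sp,
               tolerance = 1e-12)
  # dispatcher
  expect_equal(group_difference_tests(matrix(c(40, 10, 40, 10), 2))$method,
               "chisq")
  two <- group_difference_tests(c(x, y), rep(c("x", "y"), c(12, 15)))
  expect_equal(two$method, "anova")
  expect_true(is.finite(two$hedges_g))
})

test_that("ICC confidence intervals attain nominal coverage", {
  set.seed(404)
  hits <- 0
  reps <- 300
  for (i in seq_len(reps)) {
    subj <- rnorm(80)
    r <- icc_oneway(subj + rnorm(80), subj + rnorm(80))
    if (r$ci_low <= 0.5 && 0.5 <= r$ci_high) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.91)
  expect_lt(hits / reps, 0.99)
})
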
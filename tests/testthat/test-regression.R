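make_design_data <- function(n, beta = NULL, sd = 1, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    sex = rbinom(n, 1, 0.5),
    age = round(runif(n, 18, 90)),
    education01 = rbinom(n, 1, 0.4),
    setting01 = rbinom(n, 1, 0.5),
    income01 = rbinom(n, 1, 0.6)
  )
  if (is.null(beta)) {
    beta <- c(intercept = 1, sex = 0.2, age = -0.002, education01 = 0.05,
              setting01 = 0.2, income01 = 0.25,
              "education01:sex" = -0.15, "income01:sex" = -0.2)
  }
  d$net <- with(d, beta["intercept"] + beta["sex"] * sex + beta["age"] * age +
                  beta["education01"] * education01 +
                  beta["setting01"] * setting01 + beta["income01"] * income01 +
                  beta["education01:sex"] * education01 * sex +
                  beta["income01:sex"] * income01 * sex) +
    rnorm(n, sd = sd)
  d
}

test_that("noiseless data is recovered exactly with R squared 1", {
  d <- make_design_data(300, sd = 0)
  fit <- suppressWarnings(fit_linear_model(d, drm_design()))
  expect_equal(fit$r_squared, 1)
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["sex"]), 0.2, tolerance = 1e-8)
  expect_equal(unname(est["sex:income01"]), -0.2, tolerance = 1e-8)
  expect_equal(unname(est["education01:setting01"]), 0, tolerance = 1e-8)
})

test_that("residuals are orthogonal to the design", {
  d <- make_design_data(400, sd = 1, seed = 2)
  fit <- fit_linear_model(d, drm_design())
  X <- model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(X, residuals(fit$fit)))), 1e-8)
})

test_that("the nested F test matches the hand RSS formula", {
  d <- make_design_data(120, sd = 1, seed = 3)
  full <- fit_linear_model(d, drm_design())
  red <- fit_linear_model(d, drm_design(interactions = character(0)))
  res <- nested_f_test(full, red)
  df1 <- length(full$design$interactions)
  df2 <- full$n - nrow(full$coefficients)
  f_hand <- ((red$rss - full$rss) / df1) / (full$rss / df2)
  expect_equal(res$f, f_hand, tolerance = 1e-12)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(res$p, pf(f_hand, df1, df2, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical models: F = 0, p = 1
  same <- nested_f_test(full, full)
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  # non-nested rejected
  other <- fit_linear_model(d[1:100, ], drm_design())
  expect_error(nested_f_test(full, other), "nested")
})

test_that("coefficients are equivariant to flipping a 0/1 coding", {
  d <- make_design_data(200, sd = 0.5, seed = 4)
  base <- fit_linear_model(d, drm_design(interactions = character(0)))
  flip <- d
  flip$setting01 <- 1 - flip$setting01
  flipped <- fit_linear_model(flip, drm_design(interactions = character(0)))
  cf <- function(f, t) f$coefficients$estimate[f$coefficients$term == t]
  expect_equal(cf(flipped, "setting01"), -cf(base, "setting01"),
               tolerance = 1e-10)
  expect_equal(cf(flipped, "(Intercept)"),
               cf(base, "(Intercept)") + cf(base, "setting01"),
               tolerance = 1e-10)
  expect_equal(flipped$r_squared, base$r_squared, tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the aliased term", {
  d <- make_design_data(100, sd = 1, seed = 5)
  d$income01 <- d$setting01
  expect_error(fit_linear_model(d, drm_design()), "alias")
})

test_that("pruning keeps main effects and drops weak interactions", {
  # strong true interactions at large n: both retained
  d <- make_design_data(2000, sd = 0.4, seed = 6)
  fit <- fit_linear_model(d, drm_design())
  final <- prune_to_final_model(fit)
  expect_true(all(c("sex", "age", "education01", "setting01", "income01")
                  %in% final$main))
  expect_true("sex:income01" %in% final$interactions)
  # null interactions: usually all pruned; always a subset of the initial set
  d0 <- make_design_data(500, sd = 1, seed = 7,
                         beta = c(intercept = 1, sex = 0.2, age = 0,
                                  education01 = 0, setting01 = 0.2,
                                  income01 = 0.25, "education01:sex" = 0,
                                  "income01:sex" = 0))
  f0 <- fit_linear_model(d0, drm_design())
  p0 <- prune_to_final_model(f0)
  expect_true(all(p0$interactions %in% f0$design$interactions))
  # forcing alpha to 1 retains everything; alpha ~ 0 retains nothing
  expect_length(prune_to_final_model(f0, alpha = 1e-12)$interactions, 0)
  expect_length(prune_to_final_model(fit, alpha = 1 - 1e-12)$interactions, 6)
})

test_that("the overall F p-value is uniform under a permuted response", {
  set.seed(8)
  d <- make_design_data(150, sd = 1, seed = 8)
  reps <- 200
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    d$net <- sample(d$net)
    p[i] <- fit_linear_model(d, drm_design(interactions = character(0)))$f_p
  }
  expect_lt(abs(mean(p) - 0.5), 0.07)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.045)
})
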
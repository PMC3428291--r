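test_that("generation is deterministic in the seed", {
  cfg <- cohort_config(n_respondents = 80)
  a <- generate_study(cfg, seed = 5)
  b <- generate_study(cfg, seed = 5)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$segments, b$segments)
  expect_identical(a$respondents, b$respondents)
  expect_identical(a$supplementary, b$supplementary)
  c <- generate_study(cfg, seed = 6)
  expect_false(identical(a$episodes, c$episodes))
})

test_that("generated studies pass the data-model validation", {
  study <- small_cohort(n = 150, seed = 2)
  expect_silent(validate_study(study))
  # structural expectations of the design
  sets <- respondent_sets(study)
  expect_setequal(sets$respondent_id, study$respondents$respondent_id)
  retest <- study$episodes[study$episodes$wave == "retest", ]
  expect_true(all(retest$set == "FULL"))
  n_drop <- round(150 * 22 / 1560)
  expect_equal(length(unique(retest$respondent_id)), 150 - n_drop)
  # set D never appears in the episode table
  expect_false(any(study$episodes$set == "D"))
  expect_true(all(sets$set[sets$respondent_id %in%
                             study$segments$respondent_id] == "D"))
})

test_that("episodes tile each period without gaps or overlap", {
  study <- small_cohort(n = 60, seed = 8)
  ep <- study$episodes
  key <- paste(ep$respondent_id, ep$wave, ep$period)
  for (k in unique(key)) {
    e <- ep[key == k, ]
    e <- e[order(e$start_min), ]
    expect_true(all(e$end_min > e$start_min))
    if (nrow(e) > 1) {
      expect_equal(e$start_min[-1], e$end_min[-nrow(e)])
    }
    if (e$period[1] == "afternoon") {
      expect_equal(e$start_min[1], 720)
      expect_equal(e$end_min[nrow(e)], 1080)
    }
    if (e$period[1] == "morning") expect_equal(e$end_min[nrow(e)], 720)
    if (e$period[1] == "evening") expect_equal(e$start_min[1], 1080)
  }
})

test_that("the no-noise limit yields perfect downstream reliability", {
  cfg <- cohort_config(n_respondents = 120, sigma_within = 0,
                       sigma_episode = 0, sigma_item = 0,
                       activity_offsets = setNames(
                         rep(0, 22), drm_activities()$code),
                       dropout_rate = 0)
  study <- generate_study(cfg, seed = 3)
  m <- matched_scores(study)
  expect_equal(m$net_test, m$net_retest, tolerance = 1e-12)
  icc <- icc_oneway(m$net_test, m$net_retest)
  expect_equal(icc$icc, 1, tolerance = 1e-9)
})

test_that("the latent thresholds put item marginals near their targets", {
  study <- generate_study(cohort_config(n_respondents = 600), seed = 12,
                          include_retest = FALSE)
  sc <- score_study(study)
  expect_lt(abs(mean(sc$pa) - 2.2), 0.15)
  expect_lt(abs(mean(sc$na) - 1.15), 0.1)
  expect_lt(abs(mean(sc$net) - 1.05), 0.2)
})

test_that("increasing between-person variance raises the recovered ICC", {
  mean_icc <- function(sb) {
    vals <- vapply(1:12, function(i) {
      cfg <- cohort_config(n_respondents = 250, sigma_between = sb)
      m <- matched_scores(generate_study(cfg, seed = 1000 * sb + i,
                                         validate = FALSE))
      icc_oneway(m$net_test, m$net_retest)$icc
    }, numeric(1))
    mean(vals)
  }
  iccs <- vapply(c(0.2, 0.6, 1.2), mean_icc, numeric(1))
  expect_true(all(diff(iccs) > 0))
})

test_that("supplementary answers track their flip-model ground truth", {
  # flip probability zero: perfect diagonal, kappa = Delta = 1
  bi0 <- default_binary_items()
  bi0$flip <- 0
  cfg0 <- cohort_config(n_respondents = 200, binary_items = bi0)
  sup0 <- generate_supplementary(cfg0)
  d0 <- sup0[sup0$item == "worried", ]
  tab0 <- table(factor(d0$test, 0:1), factor(d0$retest, 0:1))
  expect_equal(delta_2x2(tab0)$delta, 1)
  expect_equal(sum(diag(tab0)), nrow(d0))

  # symmetric flip model: closed-form kappa target
  set.seed(99)
  bi <- data.frame(item = "x", prevalence = 0.5, flip = 0.1)
  cfg <- cohort_config(n_respondents = 1500, binary_items = bi,
                       ordinal3_items = default_ordinal3_items()[0, ])
  sup <- generate_supplementary(cfg)
  tab <- table(factor(sup$test, 0:1), factor(sup$retest, 0:1))
  f <- 0.1; pi0 <- 0.5
  po <- (1 - f)^2 + f^2
  pm <- pi0 * (1 - f) + (1 - pi0) * f
  pe <- pm^2 + (1 - pm)^2
  kappa_theory <- (po - pe) / (1 - pe)   # (1 - 2f)^2 at pi = 0.5
  expect_equal(kappa_theory, (1 - 2 * f)^2, tolerance = 1e-12)
  expect_lt(abs(cohen_kappa(tab)$kappa - kappa_theory), 0.05)

  # flip 0.5 with balanced prevalence: independence, kappa ~ 0
  bi5 <- data.frame(item = "x", prevalence = 0.5, flip = 0.5)
  cfg5 <- cohort_config(n_respondents = 1500, binary_items = bi5,
                        ordinal3_items = default_ordinal3_items()[0, ])
  sup5 <- generate_supplementary(cfg5)
  tab5 <- table(factor(sup5$test, 0:1), factor(sup5$retest, 0:1))
  expect_lt(abs(cohen_kappa(tab5)$kappa), 0.06)
})

test_that("config validation rejects malformed parameters", {
  expect_error(cohort_config(set_probs = c(A = 0.5, B = 0.5, C = 0.5,
                                           D = -0.5)), "\\[0, 1\\]")
  expect_error(cohort_config(set_probs = c(A = 0.3, B = 0.3, C = 0.3,
                                           D = 0.3)), "sum to 1")
  expect_error(cohort_config(sigma_between = -1), ">= 0")
  off <- default_activity_offsets()
  off[1] <- 3
  expect_error(cohort_config(activity_offsets = off), "\\[-2, 2\\]")
  expect_error(cohort_config(activity_offsets = off[-1][-1]), "catalog")
})

test_that("raising an activity's latent offset raises its recovered rank", {
  base_cfg <- cohort_config(n_respondents = 1200)
  boosted <- default_activity_offsets()
  boosted["watching_children"] <- 0.8   # default is strongly negative
  boost_cfg <- cohort_config(n_respondents = 1200,
                             activity_offsets = boosted)
  rank_of <- function(cfg, seed) {
    study <- generate_study(cfg, seed = seed, validate = FALSE)
    res <- rank_and_correlate(activity_table(study), min_pct = 5)
    r <- res$rankings
    match("watching_children", r$activity)
  }
  expect_lt(rank_of(boost_cfg, 41), rank_of(base_cfg, 41))
})
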
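# Independent oracles used to pin the estimators.  These deliberately
# take the dumbest correct route (loops, enumeration, stats::aov) so
# they share no code with the implementation under test.

# One-way ICC through R's ANOVA machinery on long-format data.
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  long <- data.frame(value = c(x, y),
                     subject = factor(rep(seq_len(n), 2)))
  tab <- summary(stats::aov(value ~ subject, data = long))[[1]]
  msb <- tab[["Mean Sq"]][1]
  msw <- tab[["Mean Sq"]][2]
  (msb - msw) / (msb + msw)
}

# Pairwise-concordance AUC by explicit double loop.
oracle_auc_bruteforce <- function(gold, test) {
  n <- length(gold)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (gold[i] == gold[j]) next
      den <- den + 1
      if (test[i] == test[j]) {
        num <- num + 0.5
      } else if ((test[i] - test[j]) * (gold[i] - gold[j]) > 0) {
        num <- num + 1
      }
    }
  }
  num / den
}

# U-statistic structural-components variance of the concordance AUC
# (no gold ties assumed): Var ~ 4 * var(V_i) / n with V_i the mean
# kernel of subject i against everyone else.
oracle_auc_se_ustat <- function(gold, test) {
  n <- length(gold)
  v <- numeric(n)
  for (i in seq_len(n)) {
    ks <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i || gold[i] == gold[j]) next
      k <- if (test[i] == test[j]) 0.5
           else if ((test[i] - test[j]) * (gold[i] - gold[j]) > 0) 1
           else 0
      ks <- c(ks, k)
    }
    v[i] <- mean(ks)
  }
  sqrt(4 * stats::var(v) / n)
}

# Cohen's kappa by direct cell loops.
oracle_kappa <- function(m) {
  n <- sum(m)
  k <- nrow(m)
  po <- 0; pe <- 0
  for (i in seq_len(k)) {
    po <- po + m[i, i] / n
    pe <- pe + sum(m[i, ]) * sum(m[, i]) / n^2
  }
  (po - pe) / (1 - pe)
}

# Weighted kappa by the sum-over-cells formula.
oracle_weighted_kappa <- function(m, quadratic = FALSE) {
  n <- sum(m)
  k <- nrow(m)
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- abs(i - j) / (k - 1)
      if (quadratic) w <- w^2
      num <- num + w * m[i, j] / n
      den <- den + w * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
    }
  }
  1 - num / den
}

# Maximum-likelihood fit of the 2x2 Delta model by nested grid search
# over the genuine-agreement probabilities (d1, d2); refined to ~1e-8.
oracle_delta_grid <- function(m) {
  ll <- function(d1, d2) {
    g <- (1 - d1 - d2) / 4
    p <- c(d1 + g, g, g, d2 + g)
    x <- c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    if (any(p < 0) || any(p == 0 & x > 0)) return(-Inf)
    sum(x[x > 0] * log(p[x > 0]))
  }
  lo1 <- lo2 <- -1; hi1 <- hi2 <- 1
  for (pass in 1:12) {
    g1 <- seq(lo1, hi1, length.out = 41)
    g2 <- seq(lo2, hi2, length.out = 41)
    best <- c(-Inf, NA, NA)
    for (a in g1) for (b in g2) {
      v <- ll(a, b)
      if (v > best[1]) best <- c(v, a, b)
    }
    st1 <- g1[2] - g1[1]; st2 <- g2[2] - g2[1]
    lo1 <- best[2] - st1; hi1 <- best[2] + st1
    lo2 <- best[3] - st2; hi2 <- best[3] + st2
  }
  list(delta = best[2] + best[3], d = best[2:3], loglik = best[1])
}

# Build a rating row (all seven items) from shorthand.
ratings_row <- function(worried = 1, rushed = 1, irritated_angry = 1,
                        depressed = 1, tense_stressed = 1,
                        calm_relaxed = 1, enjoyment = 1) {
  data.frame(worried = worried, rushed = rushed,
             irritated_angry = irritated_angry, depressed = depressed,
             tense_stressed = tense_stressed, calm_relaxed = calm_relaxed,
             enjoyment = enjoyment)
}

# Minimal hand-checkable study: three A/B/C respondents plus one set-D
# respondent, test and full retest waves.
tiny_study <- function() {
  ep <- rbind(
    cbind(data.frame(respondent_id = "P1", wave = "test", set = "A",
                     period = "morning", start_min = 400, end_min = 460,
                     activities = "eating", companions = "alone"),
          ratings_row(calm_relaxed = 3, enjoyment = 3)),
    cbind(data.frame(respondent_id = "P1", wave = "test", set = "A",
                     period = "morning", start_min = 460, end_min = 580,
                     activities = "working;chatting", companions = "coworkers"),
          ratings_row(worried = 2, calm_relaxed = 2, enjoyment = 2)),
    cbind(data.frame(respondent_id = "P2", wave = "test", set = "B",
                     period = "afternoon", start_min = 720, end_min = 840,
                     activities = "rest", companions = "alone"),
          ratings_row(depressed = 3, tense_stressed = 2)),
    cbind(data.frame(respondent_id = "P3", wave = "test", set = "C",
                     period = "evening", start_min = 1100, end_min = 1220,
                     activities = "eating", companions = "other_family"),
          ratings_row(calm_relaxed = 2, enjoyment = 3)),
    # full retests
    cbind(data.frame(respondent_id = c("P1", "P1", "P1"), wave = "retest",
                     set = "FULL",
                     period = c("morning", "afternoon", "evening"),
                     start_min = c(400, 720, 1080),
                     end_min = c(720, 1080, 1300),
                     activities = c("eating", "working", "rest"),
                     companions = "alone"),
          ratings_row(worried = c(1, 2, 1), calm_relaxed = c(3, 2, 2),
                      enjoyment = c(2, 2, 3))),
    cbind(data.frame(respondent_id = c("P2", "P2"), wave = "retest",
                     set = "FULL", period = c("morning", "afternoon"),
                     start_min = c(420, 720), end_min = c(700, 1050),
                     activities = c("housework", "rest"),
                     companions = "alone"),
          ratings_row(depressed = c(2, 3), calm_relaxed = c(1, 1),
                      enjoyment = c(2, 1))),
    cbind(data.frame(respondent_id = "P3", wave = "retest", set = "FULL",
                     period = "evening", start_min = 1090, end_min = 1250,
                     activities = "eating;chatting", companions = "friends"),
          ratings_row(calm_relaxed = 3, enjoyment = 2)),
    cbind(data.frame(respondent_id = "P4", wave = "retest", set = "FULL",
                     period = "morning", start_min = 400, end_min = 700,
                     activities = "rest", companions = "alone"),
          ratings_row(calm_relaxed = 2, enjoyment = 2))
  )
  sg <- cbind(
    data.frame(respondent_id = "P4", wave = "test",
               period = c("morning", "afternoon", "evening"),
               activities = c("rest", "eating", "chatting")),
    ratings_row(worried = c(1, 1, 2), calm_relaxed = c(2, 3, 1),
                enjoyment = c(2, 3, 1))
  )
  rs <- data.frame(
    respondent_id = c("P1", "P2", "P3", "P4"),
    sex = c(0, 1, 0, 1), age = c(45, 60, 38, 71),
    education_raw = c("primary", "no_formal", "college", "no_formal"),
    education01 = c(1, 0, 1, 0),
    marital = "married_or_partnership",
    setting01 = c(1, 0, 0, 1), income_quintile = c(4, 1, 3, 2),
    income01 = c(1, 0, 1, 0)
  )
  drm_study(episodes = ep, respondents = rs, segments = sg)
}

# Fast small cohort for pipeline-level tests.
small_cohort <- function(n = 150, seed = 11, ...) {
  generate_study(cohort_config(n_respondents = n, ...), seed = seed)
}
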
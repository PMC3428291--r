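# Truncated-normal draw by clamping to the admissible range; adequate
# for the mild truncation used here (tails carry little mass).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

education_levels <- function() {
  c("no_formal", "less_than_primary", "primary", "secondary", "high_school",
    "college", "postgraduate")
}

generate_respondents <- function(cfg) {
  n <- cfg$n_respondents
  id <- sprintf("R%05d", seq_len(n))
  sex <- stats::rbinom(n, 1, 1 - cfg$p_female)
  age <- round(rnorm_trunc(n, cfg$age_mean, cfg$age_sd,
                           cfg$age_range[1], cfg$age_range[2]))
  education_raw <- sample(education_levels(), n, replace = TRUE,
                          prob = cfg$education_probs)
  education01 <- as.integer(!education_raw %in% c("no_formal",
                                                  "less_than_primary"))
  marital <- ifelse(stats::rbinom(n, 1, cfg$p_married) == 1,
                    "married_or_partnership", "other")
  setting01 <- stats::rbinom(n, 1, cfg$p_urban)
  income_quintile <- sample(1:5, n, replace = TRUE,
                            prob = cfg$income_quintile_probs)
  income01 <- as.integer(income_quintile >= 3)
  data.frame(respondent_id = id, sex = sex, age = age,
             education_raw = education_raw, education01 = education01,
             marital = marital, setting01 = setting01,
             income_quintile = income_quintile, income01 = income01,
             stringsAsFactors = FALSE)
}

demographic_predictor <- function(cfg, rs) {
  b <- cfg$betas
  (b[["sex"]] * rs$sex + b[["education01"]] * rs$education01 +
     b[["setting01"]] * rs$setting01 + b[["income01"]] * rs$income01 +
     b[["age10"]] * (rs$age - cfg$age_mean) / 10 +
     b[["education01:sex"]] * rs$education01 * rs$sex +
     b[["income01:sex"]] * rs$income01 * rs$sex)
}

# Integer episode durations filling [0, len] for each group: every
# episode gets at least one minute, the rest is split proportionally to
# log-normal draws, and the rounding deficit goes to the leading
# episodes of each group.
fill_durations <- function(grp, len, sdlog) {
  raw <- stats::rlnorm(length(grp), 0, sdlog)
  tot <- stats::ave(raw, grp, FUN = sum)
  n_ep <- stats::ave(raw, grp, FUN = length)
  base <- floor(raw / tot * (len - n_ep))
  dur <- 1 + base
  deficit <- len - stats::ave(dur, grp, FUN = sum)
  within <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  dur + as.integer(within <= deficit)
}

draw_activities <- function(cfg, n) {
  codes <- names(cfg$activity_weights)
  prob <- cfg$activity_weights / sum(cfg$activity_weights)
  a1 <- sample(codes, n, replace = TRUE, prob = prob)
  a2 <- sample(codes, n, replace = TRUE, prob = prob)
  second <- stats::rbinom(n, 1, cfg$p_second_activity) == 1 & a2 != a1
  ifelse(second, paste(a1, a2, sep = ";"), a1)
}

# Mean latent offset of a semicolon-joined activity field.
activity_offset_of <- function(cfg, activities) {
  codes <- split_codes(activities)
  vapply(codes, function(v) mean(cfg$activity_offsets[v]), numeric(1))
}

# Threshold a latent episode value into the seven 1-3 item ratings.
rate_items <- function(cfg, latent) {
  n <- length(latent)
  items <- drm_affect_items()
  out <- list()
  for (it in items$positive) {
    v <- latent + stats::rnorm(n, 0, cfg$sigma_item)
    out[[it]] <- findInterval(v, cfg$pos_cut) + 1L
  }
  for (it in items$negative) {
    v <- -latent + stats::rnorm(n, 0, cfg$sigma_item)
    out[[it]] <- findInterval(v, cfg$neg_cut) + 1L
  }
  as.data.frame(out)[all_affect_items()]
}

#' Generate a synthetic abbreviated-DRM study
#'
#' Simulates a full test-retest study under a [cohort_config()]:
#' respondents are assigned to sets A-D at baseline (episode-by-episode
#' reporting of one part of the day for A-C, three whole-of-period
#' segments for D) and re-interviewed with the full-day instrument,
#' minus a completely-at-random dropout.  Episode affect follows the
#' latent-threshold model described in [cohort_config()]; all latent
#' parameters and per-respondent traits are attached as ground truth.
#' Output is deterministic given `seed`.
#'
#' @param config A `cohort_config`.
#' @param seed Integer seed driving all randomness.
#' @param include_retest Generate the retest wave (default `TRUE`;
#'   disable for cheaper baseline-only simulations).
#' @param validate Run [validate_study()] on the result (default
#'   `TRUE`).
#' @return A `drm_study` with `ground_truth` attached.
#' @export
#' @examples
#' study <- generate_study(cohort_config(n_respondents = 40), seed = 1)
#' study
generate_study <- function(config, seed = 1L, include_retest = TRUE,
                           validate = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config
  rs <- generate_respondents(cfg)
  n <- nrow(rs)
  sets <- sample(names(cfg$set_probs), n, replace = TRUE,
                 prob = cfg$set_probs)
  lp <- demographic_predictor(cfg, rs)
  trait <- stats::rnorm(n, 0, cfg$sigma_between)
  wave_noise <- list(test = stats::rnorm(n, 0, cfg$sigma_within),
                     retest = stats::rnorm(n, 0, cfg$sigma_within))
  wake <- round(rnorm_trunc(n, cfg$wake_mean, cfg$wake_sd, 300, 690))
  bed <- round(rnorm_trunc(n, cfg$bed_mean, cfg$bed_sd, 1140, 1560))

  n_drop <- round(n * cfg$dropout_rate)
  dropped <- if (n_drop > 0) sample(rs$respondent_id, n_drop) else character(0)

  base_lat <- cfg$mu + lp + trait
  set_period <- c(A = "morning", B = "afternoon", C = "evening")
  period_bounds <- function(period, idx) {
    switch(period,
           morning = cbind(wake[idx], 720),
           afternoon = cbind(rep(720, length(idx)), 1080),
           evening = cbind(rep(1080, length(idx)), bed[idx]))
  }

  # (respondent, wave, period) blocks that need episode records
  blocks <- list()
  for (s in c("A", "B", "C")) {
    idx <- which(sets == s)
    if (length(idx)) {
      blocks[[s]] <- data.frame(idx = idx, wave = "test", set = s,
                                period = set_period[[s]])
    }
  }
  if (include_retest) {
    keep <- which(!rs$respondent_id %in% dropped)
    for (p in drm_periods()) {
      blocks[[paste0("full_", p)]] <- data.frame(idx = keep, wave = "retest",
                                                 set = "FULL", period = p)
    }
  }
  blk <- do.call(rbind, blocks)

  episodes <- NULL
  if (!is.null(blk) && nrow(blk)) {
    n_ep <- sample(cfg$eps_per_period[1]:cfg$eps_per_period[2], nrow(blk),
                   replace = TRUE)
    erow <- blk[rep(seq_len(nrow(blk)), n_ep), , drop = FALSE]
    grp <- rep(seq_len(nrow(blk)), n_ep)
    bounds <- matrix(NA_real_, nrow(blk), 2)
    for (p in drm_periods()) {
      sel <- blk$period == p
      if (any(sel)) bounds[sel, ] <- period_bounds(p, blk$idx[sel])
    }
    len <- (bounds[, 2] - bounds[, 1])[grp]
    dur <- fill_durations(grp, len, cfg$duration_sdlog)
    cum <- stats::ave(dur, grp, FUN = cumsum)
    start0 <- bounds[grp, 1]
    start <- start0 + cum - dur
    end <- start0 + cum
    activities <- draw_activities(cfg, nrow(erow))
    companions <- sample(drm_companions(), nrow(erow), replace = TRUE,
                         prob = c(0.30, 0.20, 0.10, 0.20, 0.12, 0.05, 0.03))
    latent <- (base_lat[erow$idx] +
                 ifelse(erow$wave == "test", wave_noise$test[erow$idx],
                        wave_noise$retest[erow$idx]) +
                 activity_offset_of(cfg, activities) +
                 stats::rnorm(nrow(erow), 0, cfg$sigma_episode))
    ratings <- rate_items(cfg, latent)
    episodes <- cbind(
      data.frame(respondent_id = rs$respondent_id[erow$idx],
                 wave = erow$wave, set = erow$set, period = erow$period,
                 start_min = start, end_min = end,
                 activities = activities, companions = companions,
                 stringsAsFactors = FALSE),
      ratings
    )
    episodes <- episodes[order(episodes$respondent_id, episodes$wave,
                               episodes$start_min), ]
    rownames(episodes) <- NULL
  } else {
    episodes <- empty_episodes()
  }

  # set D: one segment per part of day, no durations
  segments <- empty_segments()
  idx_d <- which(sets == "D")
  if (length(idx_d)) {
    srow <- expand.grid(idx = idx_d, period = drm_periods(),
                        stringsAsFactors = FALSE)
    activities <- draw_activities(cfg, nrow(srow))
    latent <- (base_lat[srow$idx] + wave_noise$test[srow$idx] +
                 activity_offset_of(cfg, activities) +
                 stats::rnorm(nrow(srow), 0, cfg$sigma_episode))
    segments <- cbind(
      data.frame(respondent_id = rs$respondent_id[srow$idx], wave = "test",
                 period = srow$period, activities = activities,
                 stringsAsFactors = FALSE),
      rate_items(cfg, latent)
    )
    segments <- segments[order(segments$respondent_id,
                               match(segments$period, drm_periods())), ]
    rownames(segments) <- NULL
  }

  supplementary <- generate_supplementary(cfg, rs$respondent_id)
  if (length(dropped)) {
    supplementary$retest[supplementary$respondent_id %in% dropped] <- NA
    supplementary <- supplementary[!is.na(supplementary$retest), ]
    rownames(supplementary) <- NULL
  }

  ground_truth <- list(
    seed = seed,
    mu = cfg$mu, betas = as.list(cfg$betas),
    sigma_between = cfg$sigma_between, sigma_within = cfg$sigma_within,
    sigma_episode = cfg$sigma_episode, sigma_item = cfg$sigma_item,
    activity_offsets = as.list(cfg$activity_offsets),
    latent_mean = cfg$latent_mean, latent_sd = cfg$latent_sd,
    dropped = dropped,
    traits = data.frame(respondent_id = rs$respondent_id, set = sets,
                        trait = trait, linear_predictor = lp,
                        stringsAsFactors = FALSE)
  )

  study <- structure(
    list(episodes = episodes, segments = segments, respondents = rs,
         supplementary = supplementary, ground_truth = ground_truth),
    class = "drm_study"
  )
  if (validate) validate_study(study)
  study
}

#' Generate supplementary-question answers for both waves
#'
#' Yes/no items: each respondent holds a stable latent answer drawn
#' from the item's prevalence, reported in each wave with an
#' independent item-specific flip probability.  3-point items: a stable
#' latent category; with the flip probability the reported answer moves
#' to one of the other two categories (uniformly).
#'
#' @param config A `cohort_config`.
#' @param respondent_ids Character ids; defaults to
#'   `config$n_respondents` generated ids.
#' @return Long data frame: `respondent_id`, `item`, `type`, `test`,
#'   `retest`.
#' @export
generate_supplementary <- function(config, respondent_ids = NULL) {
  cfg <- config
  if (is.null(respondent_ids)) {
    respondent_ids <- sprintf("R%05d", seq_len(cfg$n_respondents))
  }
  n <- length(respondent_ids)
  out <- list()
  bi <- cfg$binary_items
  for (i in seq_len(nrow(bi))) {
    latent <- stats::rbinom(n, 1, bi$prevalence[i])
    flip_t <- stats::rbinom(n, 1, bi$flip[i])
    flip_r <- stats::rbinom(n, 1, bi$flip[i])
    out[[bi$item[i]]] <- data.frame(
      respondent_id = respondent_ids, item = bi$item[i], type = "binary",
      test = as.integer(xor(latent, flip_t)),
      retest = as.integer(xor(latent, flip_r)),
      stringsAsFactors = FALSE
    )
  }
  oi <- cfg$ordinal3_items
  flip3 <- function(latent, flip) {
    do_flip <- stats::rbinom(n, 1, flip) == 1
    shift <- sample(1:2, n, replace = TRUE)
    ifelse(do_flip, ((latent - 1 + shift) %% 3) + 1, latent)
  }
  for (i in seq_len(nrow(oi))) {
    latent <- sample(1:3, n, replace = TRUE,
                     prob = c(oi$p1[i], oi$p2[i], oi$p3[i]))
    out[[oi$item[i]]] <- data.frame(
      respondent_id = respondent_ids, item = oi$item[i], type = "ordinal3",
      test = flip3(latent, oi$flip[i]), retest = flip3(latent, oi$flip[i]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
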
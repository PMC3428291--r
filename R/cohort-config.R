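#' Default generative parameters of the synthetic cohort
#'
#' Building blocks of [cohort_config()], exported so single pieces can
#' be modified: latent affect offsets and reporting weights for the
#' 22-activity catalog, and the supplementary-question item models.
#'
#' @return `default_activity_offsets()` and
#'   `default_activity_weights()` return named numeric vectors over the
#'   activity codes; `default_binary_items()` and
#'   `default_ordinal3_items()` return the item data frames described
#'   in [cohort_config()].
#' @name cohort_defaults
NULL

#' @rdname cohort_defaults
#' @export
default_activity_offsets <- function() {
  # net-affect offsets on the latent scale, centred near zero: pleasant
  # activities (religious practice, reading, exercise) sit above the
  # mean, chores (housework, food preparation, child care) below
  c(religious_activity = 0.38, reading = 0.35, exercising_leisurely_walk = 0.31,
    grooming_bathing = 0.13, watching_tv = 0.12, chatting = 0.06,
    working = 0.04, eating = 0.02, walking_somewhere = -0.03, rest = -0.05,
    housework = -0.09, preparing_food = -0.14, watching_children = -0.21,
    intimate_relations = 0.45, listening_radio = 0.00, other_leisure = -0.05,
    playing = 0.39, providing_care = -0.40, shopping = 0.26,
    subsistence_farming = -0.64, travel_bicycle = -0.45,
    travel_car_bus_train = -0.37)
}

#' @rdname cohort_defaults
#' @export
default_activity_weights <- function() {
  # relative frequency with which activities are reported (full-day
  # reporting percentages), used as sampling weights
  c(religious_activity = 51.7, reading = 19.9, exercising_leisurely_walk = 19.6,
    grooming_bathing = 82.3, watching_tv = 40.9, chatting = 81.5,
    working = 42.7, eating = 95.7, walking_somewhere = 24.4, rest = 95.5,
    housework = 53.4, preparing_food = 23.7, watching_children = 24.3,
    intimate_relations = 0.1, listening_radio = 5.5, other_leisure = 10.6,
    playing = 1.1, providing_care = 5.1, shopping = 5.3,
    subsistence_farming = 6.2, travel_bicycle = 0.3,
    travel_car_bus_train = 0.7)
}

#' @rdname cohort_defaults
#' @export
default_binary_items <- function() {
  data.frame(
    item = c("worried", "bored", "sleepy", "depressed", "physical_pain",
             "headache", "smile", "laugh", "well_rested", "calm",
             "stressed", "rushed", "enjoyed_oneself", "lonely"),
    prevalence = c(0.35, 0.25, 0.30, 0.20, 0.45, 0.30, 0.55, 0.45, 0.60,
                   0.65, 0.25, 0.20, 0.55, 0.15),
    flip = c(0.18, 0.12, 0.12, 0.10, 0.15, 0.14, 0.16, 0.12, 0.10, 0.10,
             0.10, 0.10, 0.12, 0.08),
    stringsAsFactors = FALSE
  )
}

#' @rdname cohort_defaults
#' @export
default_ordinal3_items <- function() {
  data.frame(
    item = c("mood_vs_others", "anxiety_vs_others"),
    p1 = c(0.30, 0.25), p2 = c(0.55, 0.55), p3 = c(0.15, 0.20),
    flip = c(0.07, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic DRM cohort
#'
#' Generative parameters for a simulated abbreviated-DRM test-retest
#' study with known ground truth.  Defaults reproduce the design of the
#' validation study the generator emulates: four short sets allocated
#' with equal probability at baseline, a full-day re-interview one week
#' later, a small completely-at-random retest dropout, demographic
#' marginals shaped on a mixed urban/rural older adult sample, and a
#' latent affect model with person, wave, episode, and item variance
#' components plus activity offsets and demographic effects.
#'
#' Episode affect is generated as
#' `latent = mu + demographics + person + wave + activity + episode noise`
#' and each of the seven items is obtained by adding item noise and
#' thresholding into the 1-3 scale (positive items increase with latent
#' affect, negative items decrease).  Thresholds are calibrated from
#' the target item marginals (`pos_marginals`, `neg_marginals`) and the
#' analytic latent mean/variance, and stored in the config
#' (`pos_cut`, `neg_cut`) so they can be overridden.
#'
#' @param n_respondents Cohort size (default 1560).
#' @param set_probs Allocation probabilities of sets A-D (default 1/4
#'   each).
#' @param dropout_rate Fraction of respondents missing the retest wave
#'   (default 22/1560), removed completely at random.
#' @param mu Latent grand mean of net affect.
#' @param sigma_between,sigma_within,sigma_episode,sigma_item Standard
#'   deviations of the person trait, respondent-wave (day) noise,
#'   episode noise, and item noise.
#' @param betas Named vector of demographic effects on latent affect:
#'   `sex`, `education01`, `setting01`, `income01`, `age10` (per decade,
#'   age centred), and the interactions `education01:sex`,
#'   `income01:sex`.
#' @param activity_offsets Named latent offsets per activity code.
#' @param activity_weights Named sampling weights per activity code.
#' @param pos_marginals,neg_marginals Target marginal distributions of
#'   a positive / negative item's 1-3 ratings, used to calibrate the
#'   thresholds.
#' @param p_female,p_urban,p_married Demographic marginals.
#' @param education_probs Probabilities of the seven education
#'   categories (none, less than primary, primary, secondary, high
#'   school, college, post-graduate); "primary completed or more"
#'   becomes the 0/1 education coding.
#' @param income_quintile_probs Probabilities of the five income
#'   quintiles.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated
#'   to `age_range`.
#' @param wake_mean,wake_sd,bed_mean,bed_sd Wake-up and bedtime
#'   distributions in minutes since midnight.
#' @param eps_per_period Range (min, max) of episodes per period.
#' @param duration_sdlog Log-normal spread of raw episode durations
#'   before renormalisation to fill each period.
#' @param p_second_activity Probability an episode lists a second
#'   activity.
#' @param binary_items Data frame (`item`, `prevalence`, `flip`) for the
#'   yes/no supplementary questions: a stable latent answer is flipped
#'   independently in each wave with probability `flip`.
#' @param ordinal3_items Data frame (`item`, `p1`, `p2`, `p3`, `flip`)
#'   for the 3-point comparison questions; with probability `flip` the
#'   answer moves to one of the other two categories.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_respondents = 1560,
                          set_probs = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
                          dropout_rate = 22 / 1560,
                          mu = 1.0,
                          sigma_between = 0.6,
                          sigma_within = 0.45,
                          sigma_episode = 0.5,
                          sigma_item = 0.8,
                          betas = c(sex = 0.15, education01 = 0.05,
                                    setting01 = 0.20, income01 = 0.25,
                                    age10 = -0.02,
                                    "education01:sex" = -0.15,
                                    "income01:sex" = -0.20),
                          activity_offsets = default_activity_offsets(),
                          activity_weights = default_activity_weights(),
                          pos_marginals = c(0.15, 0.50, 0.35),
                          neg_marginals = c(0.87, 0.11, 0.02),
                          p_female = 0.531,
                          p_urban = 0.556,
                          p_married = 0.731,
                          education_probs = c(0.509, 0.068, 0.149, 0.096,
                                              0.050, 0.077, 0.051),
                          income_quintile_probs = rep(0.2, 5),
                          age_mean = 57.1, age_sd = 17.6,
                          age_range = c(18, 100),
                          wake_mean = 390, wake_sd = 45,
                          bed_mean = 1350, bed_sd = 45,
                          eps_per_period = c(2L, 4L),
                          duration_sdlog = 0.6,
                          p_second_activity = 0.12,
                          binary_items = default_binary_items(),
                          ordinal3_items = default_ordinal3_items()) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  latent <- latent_moments(cfg)
  cfg$pos_cut <- stats::qnorm(cumsum(pos_marginals)[1:2],
                              mean = latent$mean, sd = latent$sd)
  cfg$neg_cut <- stats::qnorm(cumsum(neg_marginals)[1:2],
                              mean = -latent$mean, sd = latent$sd)
  cfg$latent_mean <- latent$mean
  cfg$latent_sd <- latent$sd
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$set_probs, cfg$dropout_rate, cfg$p_female, cfg$p_urban,
             cfg$p_married, cfg$education_probs, cfg$income_quintile_probs,
             cfg$p_second_activity, cfg$pos_marginals, cfg$neg_marginals,
             cfg$binary_items$prevalence, cfg$binary_items$flip,
             cfg$ordinal3_items$p1, cfg$ordinal3_items$p2,
             cfg$ordinal3_items$p3, cfg$ordinal3_items$flip)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$set_probs) - 1) > 1e-8) {
    stop("cohort_config: set_probs must sum to 1", call. = FALSE)
  }
  sds <- c(cfg$sigma_between, cfg$sigma_within, cfg$sigma_episode,
           cfg$sigma_item)
  if (any(sds < 0)) stop("cohort_config: variance components must be >= 0",
                         call. = FALSE)
  if (cfg$n_respondents < 1) stop("cohort_config: n_respondents must be >= 1",
                                  call. = FALSE)
  known <- drm_activities()$code
  if (!setequal(names(cfg$activity_offsets), known) ||
      !setequal(names(cfg$activity_weights), known)) {
    stop("cohort_config: activity offsets/weights must cover the 22-code catalog",
         call. = FALSE)
  }
  if (any(abs(cfg$activity_offsets) > 2)) {
    stop("cohort_config: activity offsets must lie within [-2, 2]",
         call. = FALSE)
  }
  invisible(cfg)
}

# Analytic mean and sd of the episode-item latent value under the
# config, used to place the rating thresholds.  The demographic part is
# enumerated exactly over the 16 combinations of the four binary
# predictors; age contributes variance only (it is centred).
latent_moments <- function(cfg) {
  grid <- expand.grid(sex = 0:1, education01 = 0:1, setting01 = 0:1,
                      income01 = 0:1)
  p_male <- 1 - cfg$p_female
  p_educ <- sum(cfg$education_probs[3:7]) / sum(cfg$education_probs)
  p_inc <- sum(cfg$income_quintile_probs[3:5]) / sum(cfg$income_quintile_probs)
  w <- (ifelse(grid$sex == 1, p_male, 1 - p_male) *
          ifelse(grid$education01 == 1, p_educ, 1 - p_educ) *
          ifelse(grid$setting01 == 1, cfg$p_urban, 1 - cfg$p_urban) *
          ifelse(grid$income01 == 1, p_inc, 1 - p_inc))
  b <- cfg$betas
  lp <- (b[["sex"]] * grid$sex + b[["education01"]] * grid$education01 +
           b[["setting01"]] * grid$setting01 + b[["income01"]] * grid$income01 +
           b[["education01:sex"]] * grid$education01 * grid$sex +
           b[["income01:sex"]] * grid$income01 * grid$sex)
  m_lp <- sum(w * lp)
  v_lp <- sum(w * (lp - m_lp)^2) + (b[["age10"]] * cfg$age_sd / 10)^2
  aw <- cfg$activity_weights / sum(cfg$activity_weights)
  off <- cfg$activity_offsets[names(aw)]
  m_act <- sum(aw * off)
  v_act <- sum(aw * (off - m_act)^2)
  m <- cfg$mu + m_lp + m_act
  v <- v_lp + v_act + cfg$sigma_between^2 + cfg$sigma_within^2 +
    cfg$sigma_episode^2 + cfg$sigma_item^2
  list(mean = m, sd = sqrt(v))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic DRM cohort configuration\n")
  cat(sprintf("  n = %d, dropout = %.3f, sets = %s\n", x$n_respondents,
              x$dropout_rate,
              paste(sprintf("%s:%.2f", names(x$set_probs), x$set_probs),
                    collapse = " ")))
  cat(sprintf("  latent affect: mu = %.2f, sd(person) = %.2f, sd(wave) = %.2f, sd(episode) = %.2f, sd(item) = %.2f\n",
              x$mu, x$sigma_between, x$sigma_within, x$sigma_episode,
              x$sigma_item))
  cat(sprintf("  implied latent mean %.2f, sd %.2f\n", x$latent_mean,
              x$latent_sd))
  invisible(x)
}
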
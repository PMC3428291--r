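# Explode episodes so one row = one (episode, activity) pair; an episode
# listing several activities contributes its full duration and affect to
# each one.
explode_activities <- function(ep) {
  codes <- split_codes(ep$activities)
  idx <- rep(seq_len(nrow(ep)), lengths(codes))
  out <- ep[idx, , drop = FALSE]
  out$activity <- unlist(codes)
  rownames(out) <- NULL
  out
}

# Per-respondent, per-activity duration-weighted mean net affect and
# total minutes, for one wave's episodes.
respondent_activity_affect <- function(ep, ties_unpleasant = FALSE) {
  ex <- explode_activities(ep)
  net <- episode_net_affect(ex)
  complete <- !is.na(net)
  ex <- ex[complete, , drop = FALSE]
  net <- net[complete]
  dur <- ex$end_min - ex$start_min
  key <- paste(ex$respondent_id, ex$activity, sep = "\r")
  sums <- rowsum(cbind(t = dur, m = dur * net), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  data.frame(
    respondent_id = vapply(parts, `[`, character(1), 1L),
    activity = vapply(parts, `[`, character(1), 2L),
    minutes = sums[, "t"],
    net = sums[, "m"] / sums[, "t"],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Ratio-estimator standard error of a weighted mean over respondents.
weighted_mean_se <- function(values, weights) {
  n <- length(values)
  if (n < 2L) return(NA_real_)
  w <- weights / sum(weights)
  m <- sum(w * values)
  sqrt(n / (n - 1) * sum(w^2 * (values - m)^2))
}

#' Per-activity affect profile across test and retest
#'
#' For every activity in the catalog reported by the analysis sample
#' (respondents who completed an episode-based short set - A, B, or C -
#' at baseline and the full instrument at retest): the percentage of
#' respondents reporting it in each wave, the duration-weighted mean net
#' affect in each wave (the sample is weighted by the time each
#' respondent spent in the activity) with a standard error, the number
#' of respondents reporting the activity in both waves, and the
#' test-retest Pearson correlation of per-respondent activity affect
#' (computed when at least 3 respondents report the activity twice;
#' Fisher-z CI when at least 4 do).
#'
#' @param study A `drm_study`.
#' @param respondent_level Give every reporting respondent equal weight
#'   instead of weighting by time spent (default `FALSE`).
#' @param alpha Significance level for correlation CIs.
#' @return Data frame of class `activity_table` with one row per
#'   reported activity: `activity`, `pct_test`, `mean_net_test`,
#'   `se_test`, `pct_retest`, `mean_net_retest`, `se_retest`, `n_both`,
#'   `r`, `r_ci_low`, `r_ci_high`.
#' @export
activity_table <- function(study, respondent_level = FALSE, alpha = 0.05) {
  ep <- study$episodes
  sets <- respondent_sets(study)
  abc <- sets$respondent_id[sets$set %in% c("A", "B", "C")]
  retest_ids <- unique(ep$respondent_id[ep$wave == "retest"])
  pop <- intersect(abc, retest_ids)
  if (!length(pop)) stop("activity_table: no episode-based respondents with both waves",
                         call. = FALSE)
  n_pop <- length(pop)

  per_wave <- lapply(c("test", "retest"), function(wv) {
    e <- ep[ep$wave == wv & ep$respondent_id %in% pop, , drop = FALSE]
    respondent_activity_affect(e)
  })
  names(per_wave) <- c("test", "retest")

  acts <- sort(unique(c(per_wave$test$activity, per_wave$retest$activity)))
  summarize <- function(df, act) {
    d <- df[df$activity == act, , drop = FALSE]
    if (!nrow(d)) {
      return(c(pct = 0, mean_net = NA_real_, se = NA_real_))
    }
    w <- if (respondent_level) rep(1, nrow(d)) else d$minutes
    c(pct = 100 * nrow(d) / n_pop,
      mean_net = sum(w * d$net) / sum(w),
      se = weighted_mean_se(d$net, w))
  }
  rows <- lapply(acts, function(act) {
    s_t <- summarize(per_wave$test, act)
    s_r <- summarize(per_wave$retest, act)
    both <- merge(per_wave$test[per_wave$test$activity == act,
                                c("respondent_id", "net")],
                  per_wave$retest[per_wave$retest$activity == act,
                                  c("respondent_id", "net")],
                  by = "respondent_id")
    r <- r_lo <- r_hi <- NA_real_
    if (nrow(both) >= 3L &&
        stats::sd(both$net.x) > 0 && stats::sd(both$net.y) > 0) {
      r <- stats::cor(both$net.x, both$net.y)
      if (nrow(both) >= 4L) {
        ci <- pearson_fisher_ci(both$net.x, both$net.y, alpha = alpha)
        r_lo <- ci$ci_low; r_hi <- ci$ci_high
      }
    }
    data.frame(activity = act,
               pct_test = s_t[["pct"]], mean_net_test = s_t[["mean_net"]],
               se_test = s_t[["se"]],
               pct_retest = s_r[["pct"]], mean_net_retest = s_r[["mean_net"]],
               se_retest = s_r[["se"]],
               n_both = nrow(both), r = r, r_ci_low = r_lo, r_ci_high = r_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Rank activities by affect and assess ranking stability
#'
#' Restricts the [activity_table()] to activities reported at baseline
#' by at least `min_pct` percent of the sample (inclusive threshold,
#' applied to the baseline percentage only), ranks them from highest to
#' lowest baseline mean net affect (ties broken by activity code for
#' determinism), and quantifies temporal stability by the Spearman
#' correlation between the two waves' rankings and the Pearson
#' correlation of mean net affect across activities.
#'
#' @param table An `activity_table`.
#' @param min_pct Baseline reporting threshold in percent (default 5).
#' @param alpha Significance level for the Pearson CI.
#' @return List with `rankings` (the filtered table with `rank_test`,
#'   `rank_retest`), `spearman` (a `corr_result` on the rankings),
#'   `pearson_of_means` (a `corr_result` on the mean net affects), and
#'   `n_activities`.
#' @export
rank_and_correlate <- function(table, min_pct = 5, alpha = 0.05) {
  keep <- table[!is.na(table$mean_net_test) & table$pct_test >= min_pct, ,
                drop = FALSE]
  if (nrow(keep) < 3L) {
    stop("rank_and_correlate: fewer than 3 activities pass the reporting filter",
         call. = FALSE)
  }
  ord <- order(-keep$mean_net_test, keep$activity)
  keep <- keep[ord, , drop = FALSE]
  keep$rank_test <- rank(-keep$mean_net_test, ties.method = "average")
  keep$rank_retest <- rank(-keep$mean_net_retest, ties.method = "average")
  rownames(keep) <- NULL
  list(
    rankings = keep,
    spearman = spearman_rho(keep$mean_net_test, keep$mean_net_retest),
    pearson_of_means = pearson_fisher_ci(keep$mean_net_test,
                                         keep$mean_net_retest, alpha = alpha),
    n_activities = nrow(keep)
  )
}
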
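# Duration-weighted aggregation of episode-level affect by a grouping
# key.  Drops incomplete episodes (any missing item) with one summary
# warning.
aggregate_episode_scores <- function(ep, ties_unpleasant = FALSE,
                                     weighted = TRUE) {
  pa <- episode_positive_affect(ep)
  na_ <- episode_negative_affect(ep)
  unpl <- episode_is_unpleasant(ep, ties_unpleasant = ties_unpleasant)
  complete <- !is.na(pa) & !is.na(na_)
  if (any(!complete)) {
    warning(sprintf("excluded %d episode(s) with incomplete ratings",
                    sum(!complete)), call. = FALSE)
  }
  ep <- ep[complete, , drop = FALSE]
  if (!nrow(ep)) {
    return(data.frame(respondent_id = character(0), wave = character(0),
                      pa = numeric(0), na = numeric(0), net = numeric(0),
                      u_index = numeric(0), total_minutes = numeric(0),
                      n_used = integer(0)))
  }
  pa <- pa[complete]; na_ <- na_[complete]; unpl <- unpl[complete]
  w <- if (weighted) ep$end_min - ep$start_min else rep(1, nrow(ep))
  key <- paste(ep$respondent_id, ep$wave, sep = "\r")
  sums <- rowsum(cbind(w = w, pa = w * pa, na = w * na_, u = w * unpl,
                       n = 1), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(
    respondent_id = vapply(parts, `[`, character(1), 1L),
    wave = vapply(parts, `[`, character(1), 2L),
    pa = sums[, "pa"] / sums[, "w"],
    na = sums[, "na"] / sums[, "w"],
    net = (sums[, "pa"] - sums[, "na"]) / sums[, "w"],
    u_index = if (weighted) sums[, "u"] / sums[, "w"] else NA_real_,
    total_minutes = if (weighted) sums[, "w"] else NA_real_,
    n_used = as.integer(sums[, "n"]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Score every respondent-wave of a study
#'
#' Applies the set-specific scoring rules across a whole study:
#' duration-weighted PA, NA, net affect and U-index for episode-based
#' waves (sets A, B, C and the full-day retest); raw unweighted means
#' and no U-index for segment-based set-D waves.
#'
#' @param study A `drm_study`.
#' @param ties_unpleasant Passed to [episode_is_unpleasant()].
#' @return Data frame with one row per scored respondent-wave:
#'   `respondent_id`, `wave`, `set`, `pa`, `na`, `net`, `u_index`,
#'   `total_minutes`, `n_used`.
#' @export
score_study <- function(study, ties_unpleasant = FALSE) {
  sets <- respondent_sets(study)
  out <- list()
  if (nrow(study$episodes)) {
    out$ep <- aggregate_episode_scores(study$episodes, ties_unpleasant,
                                       weighted = TRUE)
  }
  if (nrow(study$segments)) {
    sg <- study$segments
    sg$start_min <- NULL
    out$sg <- aggregate_episode_scores(sg, ties_unpleasant, weighted = FALSE)
  }
  res <- do.call(rbind, out)
  res <- merge(res, sets, by = "respondent_id", all.x = TRUE, sort = FALSE)
  # the retest wave is the full instrument regardless of baseline set
  res$set[res$wave == "retest"] <- "FULL"
  res <- res[order(res$respondent_id, res$wave),
             c("respondent_id", "wave", "set", "pa", "na", "net", "u_index",
               "total_minutes", "n_used")]
  rownames(res) <- NULL
  res
}

#' Baseline scores matched with period-sliced retest scores
#'
#' Builds the respondent-level paired sample used by the test-retest
#' battery.  Each short set is compared with the analogous part of the
#' full-day retest: set A against the retest's morning slice, B against
#' the afternoon slice, C against the evening slice, and set D (whole
#' day in three segments) against the whole-day retest score.  Full-day
#' retest scores are also returned for the criterion-validity (AUC)
#' comparisons.
#'
#' @param study A `drm_study`.
#' @param ties_unpleasant Passed to [episode_is_unpleasant()].
#' @return Data frame with one row per respondent present in both
#'   waves: `respondent_id`, `set`, test-wave scores
#'   (`pa_test`, `na_test`, `net_test`, `u_test`), period-matched
#'   retest scores (`*_retest`), and whole-day retest scores
#'   (`*_full`).
#' @export
matched_scores <- function(study, ties_unpleasant = FALSE) {
  scores <- score_study(study, ties_unpleasant = ties_unpleasant)
  test <- scores[scores$wave == "test", ]
  full <- scores[scores$wave == "retest", ]

  retest_ep <- study$episodes[study$episodes$wave == "retest", , drop = FALSE]
  slices <- lapply(drm_periods(), function(p) {
    sl <- slice_full_wave(retest_ep, p)
    if (!nrow(sl)) return(NULL)
    ag <- aggregate_episode_scores(sl, ties_unpleasant, weighted = TRUE)
    ag$period <- p
    ag
  })
  slices <- do.call(rbind, slices)

  set_period <- c(A = "morning", B = "afternoon", C = "evening")
  out <- merge(
    stats::setNames(test[c("respondent_id", "set", "pa", "na", "net", "u_index")],
                    c("respondent_id", "set", "pa_test", "na_test", "net_test",
                      "u_test")),
    stats::setNames(full[c("respondent_id", "pa", "na", "net", "u_index")],
                    c("respondent_id", "pa_full", "na_full", "net_full",
                      "u_full")),
    by = "respondent_id"
  )
  out$period <- unname(set_period[out$set])

  sl <- stats::setNames(
    slices[c("respondent_id", "period", "pa", "na", "net", "u_index")],
    c("respondent_id", "period", "pa_slice", "na_slice", "net_slice",
      "u_slice"))
  out <- merge(out, sl, by = c("respondent_id", "period"), all.x = TRUE)

  # matched retest: the period slice for A/B/C, the whole day for D
  is_d <- out$set == "D"
  out$pa_retest <- ifelse(is_d, out$pa_full, out$pa_slice)
  out$na_retest <- ifelse(is_d, out$na_full, out$na_slice)
  out$net_retest <- ifelse(is_d, out$net_full, out$net_slice)
  out$u_retest <- ifelse(is_d, NA_real_, out$u_slice)
  out$u_test[is_d] <- NA_real_

  dropped <- is.na(out$net_retest)
  if (any(dropped)) {
    message(sprintf("matched_scores: %d respondent(s) with an empty matched period excluded",
                    sum(dropped)))
    out <- out[!dropped, , drop = FALSE]
  }
  out <- out[order(out$respondent_id),
             c("respondent_id", "set", "period",
               "pa_test", "na_test", "net_test", "u_test",
               "pa_retest", "na_retest", "net_retest", "u_retest",
               "pa_full", "na_full", "net_full", "u_full")]
  rownames(out) <- NULL
  out
}
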
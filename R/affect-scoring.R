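#' Affect items of the DRM episode questionnaire
#'
#' Seven feelings are rated for every episode on a 1 (not at all) to
#' 3 (very much) scale: five negative items and two positive items.
#'
#' @return Named list with character vectors `positive` and `negative`.
#' @export
drm_affect_items <- function() {
  list(
    positive = c("calm_relaxed", "enjoyment"),
    negative = c("worried", "rushed", "irritated_angry", "depressed",
                 "tense_stressed")
  )
}

all_affect_items <- function() unlist(drm_affect_items(), use.names = FALSE)

# Coerce ratings input (named vector, list, or data frame) to a data frame
# with the seven item columns, and validate the 1..3 range.  NA is allowed
# (incomplete episode); anything else outside {1,2,3} is an error naming
# the offending item.
as_ratings_df <- function(ratings) {
  items <- all_affect_items()
  if (is.data.frame(ratings)) {
    df <- ratings
  } else if (is.list(ratings) || (is.numeric(ratings) && !is.null(names(ratings)))) {
    df <- as.data.frame(as.list(ratings))
  } else {
    stop("ratings must be a data frame or a named list/vector", call. = FALSE)
  }
  missing_items <- setdiff(items, names(df))
  if (length(missing_items)) {
    stop("ratings missing item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  df <- df[items]
  for (it in items) {
    v <- df[[it]]
    bad <- !is.na(v) & !(v %in% c(1, 2, 3))
    if (any(bad)) {
      stop(sprintf("rating for item '%s' outside {1,2,3} in row(s) %s",
                   it, paste(utils::head(which(bad), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}

#' Episode-level positive affect
#'
#' Mean of the two positive items (calm/relaxed and enjoyment).
#'
#' @param ratings A data frame with one row per episode and the seven
#'   affect item columns, or a named vector/list for a single episode.
#' @return Numeric vector in `[1, 3]`; `NA` where any positive item is
#'   missing.
#' @export
#' @examples
#' episode_positive_affect(c(worried = 1, rushed = 1, irritated_angry = 1,
#'   depressed = 1, tense_stressed = 1, calm_relaxed = 3, enjoyment = 2))
episode_positive_affect <- function(ratings) {
  df <- as_ratings_df(ratings)
  rowMeans(as.matrix(df[drm_affect_items()$positive]))
}

#' Episode-level negative affect
#'
#' Mean of the five negative items (worried, rushed, irritated/angry,
#' depressed, tense/stressed).
#'
#' @inheritParams episode_positive_affect
#' @return Numeric vector in `[1, 3]`; `NA` where any negative item is
#'   missing.
#' @export
episode_negative_affect <- function(ratings) {
  df <- as_ratings_df(ratings)
  rowMeans(as.matrix(df[drm_affect_items()$negative]))
}

#' Episode-level net affect
#'
#' Positive affect minus negative affect; ranges from -2 (all positive
#' items at the floor, all negative items at the ceiling) to 2.
#'
#' @inheritParams episode_positive_affect
#' @return Numeric vector in `[-2, 2]`.
#' @export
episode_net_affect <- function(ratings) {
  episode_positive_affect(ratings) - episode_negative_affect(ratings)
}

#' Is an episode unpleasant?
#'
#' An episode is unpleasant when its highest-rated feeling is a negative
#' one: the maximum over the five negative items strictly exceeds the
#' maximum over the two positive items.  Ties count as not unpleasant
#' (the rule requires the top feeling to *be* a negative one); set
#' `ties_unpleasant = TRUE` for the alternative convention.
#'
#' @inheritParams episode_positive_affect
#' @param ties_unpleasant Count max-negative == max-positive ties as
#'   unpleasant.  Default `FALSE`.
#' @return Logical vector; `NA` where any item is missing.
#' @export
episode_is_unpleasant <- function(ratings, ties_unpleasant = FALSE) {
  df <- as_ratings_df(ratings)
  items <- drm_affect_items()
  max_neg <- do.call(pmax, c(unname(df[items$negative]), list(na.rm = FALSE)))
  max_pos <- do.call(pmax, c(unname(df[items$positive]), list(na.rm = FALSE)))
  if (ties_unpleasant) max_neg >= max_pos else max_neg > max_pos
}

#' Score one respondent-wave
#'
#' Aggregates episode (or segment) affect into the wave-level summary:
#' positive affect (PA), negative affect (NA), net affect, and - where
#' episode durations exist - the U-index, the proportion of reported time
#' spent in unpleasant episodes.
#'
#' Episode-based records (sets A, B, C and the full-day instrument) are
#' duration-weighted; segment-based records (set D) carry no durations,
#' so a raw (unweighted) mean is taken and the U-index is not defined.
#' Episodes with any missing affect item are excluded with a warning;
#' the count of exclusions is attached as attribute `n_dropped`.
#'
#' @param x Data frame of the wave's episodes (columns `start_min`,
#'   `end_min` plus the seven affect items) or segments (affect items
#'   only).
#' @param duration_weighted Use duration weights; requires `start_min` /
#'   `end_min`.  Default `TRUE` when those columns are present.
#' @param ties_unpleasant Passed to [episode_is_unpleasant()].
#' @return One-row data frame with columns `pa`, `na`, `net`, `u_index`,
#'   `total_minutes`, `n_used`, and attribute `n_dropped`.
#' @export
score_wave <- function(x,
                       duration_weighted = all(c("start_min", "end_min") %in% names(x)),
                       ties_unpleasant = FALSE) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("score_wave: wave contains no episodes or segments", call. = FALSE)
  }
  if (duration_weighted) {
    if (!all(c("start_min", "end_min") %in% names(x))) {
      stop("duration-weighted scoring requires start_min and end_min",
           call. = FALSE)
    }
    dur <- x$end_min - x$start_min
    if (any(is.na(dur)) || any(dur <= 0)) {
      stop("score_wave: malformed interval (end_min must exceed start_min)",
           call. = FALSE)
    }
  } else {
    dur <- rep(1, nrow(x))
  }
  pa <- episode_positive_affect(x)
  na_ <- episode_negative_affect(x)
  unpl <- episode_is_unpleasant(x, ties_unpleasant = ties_unpleasant)
  complete <- !is.na(pa) & !is.na(na_)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    warning(sprintf("score_wave: excluded %d episode(s) with incomplete ratings",
                    n_dropped), call. = FALSE)
  }
  if (!any(complete)) {
    stop("score_wave: no episode with complete ratings", call. = FALSE)
  }
  w <- dur[complete]
  out <- data.frame(
    pa = sum(w * pa[complete]) / sum(w),
    na = sum(w * na_[complete]) / sum(w),
    net = NA_real_,
    u_index = if (duration_weighted) {
      sum(w * unpl[complete]) / sum(w)
    } else {
      NA_real_
    },
    total_minutes = if (duration_weighted) sum(w) else NA_real_,
    n_used = sum(complete)
  )
  out$net <- out$pa - out$na
  attr(out, "n_dropped") <- n_dropped
  out
}

# Period windows under the boundary convention: morning runs from wake-up
# to noon, afternoon from noon to 18:00, evening from 18:00 onwards.
period_window <- function(period) {
  switch(period,
    morning = c(-Inf, 720),
    afternoon = c(720, 1080),
    evening = c(1080, Inf),
    stop("unknown period: ", period, call. = FALSE)
  )
}

#' Time periods of the day
#' @return Character vector `c("morning", "afternoon", "evening")`.
#' @export
drm_periods <- function() c("morning", "afternoon", "evening")

# Period containing a minute-of-day value.
period_of_minute <- function(minute) {
  cut(minute, breaks = c(-Inf, 720, 1080, Inf),
      labels = drm_periods(), right = FALSE)
}

#' Slice a full-day wave to one time period
#'
#' Restricts the episodes of a full-day record to a single period of the
#' day, so the full instrument can be compared against the short set that
#' covers the same time interval.  Episodes straddling a period boundary
#' are split at the boundary with durations prorated; ratings are carried
#' unchanged into each part.
#'
#' @param episodes Data frame of one or more full-day waves' episodes
#'   (must include `start_min`, `end_min`).
#' @param period One of `"morning"`, `"afternoon"`, `"evening"`.
#' @return Episode data frame clipped to the period window (possibly with
#'   zero rows); the `period` column, if present, is set to `period`.
#' @export
slice_full_wave <- function(episodes, period) {
  period <- match.arg(period, drm_periods())
  if (!all(c("start_min", "end_min") %in% names(episodes))) {
    stop("slice_full_wave: episodes must have start_min and end_min",
         call. = FALSE)
  }
  if ("set" %in% names(episodes) && nrow(episodes) &&
      any(episodes$set != "FULL")) {
    stop("slice_full_wave: episodes must come from a FULL (whole-day) wave",
         call. = FALSE)
  }
  win <- period_window(period)
  s <- pmax(episodes$start_min, win[1])
  e <- pmin(episodes$end_min, win[2])
  keep <- e > s
  out <- episodes[keep, , drop = FALSE]
  out$start_min <- s[keep]
  out$end_min <- e[keep]
  if ("period" %in% names(out) && nrow(out)) out$period <- period
  rownames(out) <- NULL
  out
}
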
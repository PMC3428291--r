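episode_columns <- function() {
  c("respondent_id", "wave", "set", "period", "start_min", "end_min",
    "activities", "companions", all_affect_items())
}

segment_columns <- function() {
  c("respondent_id", "wave", "period", "activities", all_affect_items())
}

respondent_columns <- function() {
  c("respondent_id", "sex", "age", "education_raw", "education01",
    "marital", "setting01", "income_quintile", "income01")
}

empty_episodes <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(episode_columns())), episode_columns()))
  num <- c("start_min", "end_min", all_affect_items())
  df[num] <- lapply(df[num], as.numeric)
  df
}

empty_segments <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(segment_columns())), segment_columns()))
  df[all_affect_items()] <- lapply(df[all_affect_items()], as.numeric)
  df
}

#' Construct and validate a DRM study
#'
#' Bundles the three (plus optional) tables of an abbreviated-DRM
#' test-retest study: episode-level records (sets A, B, C and the
#' full-day retest), segment-level records (set D, one block per part of
#' day), respondent demographics, and the supplementary yes/no and
#' 3-point questions asked at the end of each interview.
#'
#' @param episodes Episode table; see [read_study()] for the schema.
#' @param respondents Demographics table.
#' @param segments Optional set-D segment table.
#' @param supplementary Optional supplementary-question table with
#'   columns `respondent_id`, `item`, `type` (`"binary"` or
#'   `"ordinal3"`), `test`, `retest`.
#' @param ground_truth Optional list of generative parameters (attached
#'   by [generate_study()]).
#' @return Object of class `drm_study`.
#' @export
drm_study <- function(episodes, respondents, segments = NULL,
                      supplementary = NULL, ground_truth = NULL) {
  if (is.null(segments)) segments <- empty_segments()
  study <- structure(
    list(episodes = episodes, segments = segments,
         respondents = respondents, supplementary = supplementary,
         ground_truth = ground_truth),
    class = "drm_study"
  )
  validate_study(study)
  study
}

#' Validate a DRM study
#'
#' Checks schema, code catalogs, rating ranges, interval sanity,
#' duplicate keys, and set/period consistency.  Called by [drm_study()]
#' and [read_study()]; exported so externally assembled tables can be
#' checked directly.
#'
#' @param study A `drm_study` object.
#' @return The study, invisibly; errors describe the offending table and
#'   rows.
#' @export
validate_study <- function(study) {
  ep <- study$episodes
  sg <- study$segments
  rs <- study$respondents

  miss <- setdiff(episode_columns(), names(ep))
  if (length(miss)) stop("episodes: missing column(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)
  miss <- setdiff(segment_columns(), names(sg))
  if (length(miss)) stop("segments: missing column(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)
  miss <- setdiff(respondent_columns(), names(rs))
  if (length(miss)) stop("respondents: missing column(s) ", paste(miss, collapse = ", "),
                         call. = FALSE)

  if (anyDuplicated(rs$respondent_id)) {
    stop("respondents: duplicate respondent_id", call. = FALSE)
  }
  for (col in c("sex", "education01", "setting01", "income01")) {
    if (any(!rs[[col]] %in% 0:1)) {
      stop(sprintf("respondents: column '%s' must be coded 0/1", col),
           call. = FALSE)
    }
  }
  if (any(!rs$income_quintile %in% 1:5)) {
    stop("respondents: income_quintile must be in 1..5", call. = FALSE)
  }

  if (nrow(ep)) {
    if (any(!ep$wave %in% c("test", "retest"))) {
      stop("episodes: wave must be 'test' or 'retest'", call. = FALSE)
    }
    if (any(!ep$set %in% c("A", "B", "C", "FULL"))) {
      stop("episodes: set must be A, B, C, or FULL", call. = FALSE)
    }
    if (any(!ep$period %in% drm_periods())) {
      stop("episodes: unknown period", call. = FALSE)
    }
    bad <- which(!(ep$end_min > ep$start_min) | ep$start_min < 0 |
                   ep$end_min > 1800)
    if (length(bad)) {
      stop("episodes: malformed interval in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    key <- paste(ep$respondent_id, ep$wave, ep$start_min)
    if (anyDuplicated(key)) {
      stop("episodes: duplicate (respondent, wave, start_min) key in row(s) ",
           paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
           call. = FALSE)
    }
    as_ratings_df(ep)
    check_activity_codes(ep$activities, "episodes")
    if (any(!ep$respondent_id %in% rs$respondent_id)) {
      stop("episodes: respondent_id not present in respondents table",
           call. = FALSE)
    }
    # short sets cover exactly one period each
    short <- ep[ep$set %in% c("A", "B", "C"), , drop = FALSE]
    if (nrow(short)) {
      nper <- tapply(short$period, paste(short$respondent_id, short$wave),
                     function(p) length(unique(p)))
      if (any(nper > 1L)) {
        stop("episodes: a short-set wave spans more than one period",
             call. = FALSE)
      }
      expected <- c(A = "morning", B = "afternoon", C = "evening")
      if (any(short$period != expected[short$set])) {
        stop("episodes: short-set period inconsistent with set assignment",
             call. = FALSE)
      }
    }
    full <- ep[ep$set == "FULL", , drop = FALSE]
    if (nrow(full) &&
        any(as.character(period_of_minute(full$start_min)) != full$period)) {
      stop("episodes: full-wave period label inconsistent with start time",
           call. = FALSE)
    }
  }

  if (nrow(sg)) {
    if (any(!sg$wave %in% c("test", "retest"))) {
      stop("segments: wave must be 'test' or 'retest'", call. = FALSE)
    }
    if (any(!sg$period %in% drm_periods())) {
      stop("segments: unknown period", call. = FALSE)
    }
    key <- paste(sg$respondent_id, sg$wave, sg$period)
    if (anyDuplicated(key)) {
      stop("segments: more than one segment per (respondent, wave, period)",
           call. = FALSE)
    }
    as_ratings_df(sg)
    check_activity_codes(sg$activities, "segments")
    if (any(!sg$respondent_id %in% rs$respondent_id)) {
      stop("segments: respondent_id not present in respondents table",
           call. = FALSE)
    }
    both <- intersect(paste(sg$respondent_id, sg$wave),
                      paste(ep$respondent_id, ep$wave))
    if (length(both)) {
      stop("a wave cannot mix episodes and segments: ",
           paste(utils::head(both, 3L), collapse = "; "), call. = FALSE)
    }
  }

  sp <- study$supplementary
  if (!is.null(sp) && nrow(sp)) {
    need <- c("respondent_id", "item", "type", "test", "retest")
    miss <- setdiff(need, names(sp))
    if (length(miss)) stop("supplementary: missing column(s) ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (any(!sp$type %in% c("binary", "ordinal3"))) {
      stop("supplementary: type must be 'binary' or 'ordinal3'", call. = FALSE)
    }
    b <- sp$type == "binary"
    if (any(!sp$test[b] %in% 0:1) || any(!sp$retest[b] %in% 0:1)) {
      stop("supplementary: binary answers must be 0/1", call. = FALSE)
    }
    if (any(!sp$test[!b] %in% 1:3) || any(!sp$retest[!b] %in% 1:3)) {
      stop("supplementary: 3-point answers must be in 1..3", call. = FALSE)
    }
  }
  invisible(study)
}

#' Read a DRM study from delimited text files
#'
#' Reads `episodes.csv`, `respondents.csv`, and - when present -
#' `segments.csv`, `supplementary.csv`, and `ground_truth.json` from a
#' directory, validates them, and returns a [drm_study()].
#'
#' The episode schema is: `respondent_id`, `wave` (test/retest), `set`
#' (A/B/C/FULL), `period`, `start_min`, `end_min` (minutes since
#' midnight, half-open interval), `activities` and `companions`
#' (semicolon-joined codes), and the seven affect items
#' (`worried`, `rushed`, `irritated_angry`, `depressed`,
#' `tense_stressed`, `calm_relaxed`, `enjoyment`), each rated 1-3.
#'
#' @param path Directory containing the study tables.
#' @return A `drm_study` object.
#' @export
read_study <- function(path) {
  read1 <- function(name) {
    utils::read.csv(file.path(path, name), stringsAsFactors = FALSE,
                    colClasses = c(respondent_id = "character"))
  }
  episodes <- if (file.exists(file.path(path, "episodes.csv"))) {
    read1("episodes.csv")
  } else {
    empty_episodes()
  }
  segments <- if (file.exists(file.path(path, "segments.csv"))) {
    read1("segments.csv")
  } else {
    NULL
  }
  supplementary <- if (file.exists(file.path(path, "supplementary.csv"))) {
    read1("supplementary.csv")
  } else {
    NULL
  }
  ground_truth <- if (file.exists(file.path(path, "ground_truth.json"))) {
    jsonlite::fromJSON(file.path(path, "ground_truth.json"),
                       simplifyDataFrame = TRUE)
  } else {
    NULL
  }
  respondents <- read1("respondents.csv")
  drm_study(episodes = episodes, respondents = respondents,
            segments = segments, supplementary = supplementary,
            ground_truth = ground_truth)
}

#' Write a DRM study to delimited text files
#'
#' Inverse of [read_study()]; the round trip is lossless for the four
#' tables.  Ground truth, when present, is written as
#' `ground_truth.json`.
#'
#' @param study A `drm_study`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$episodes, file.path(path, "episodes.csv"),
                   row.names = FALSE)
  utils::write.csv(study$respondents, file.path(path, "respondents.csv"),
                   row.names = FALSE)
  if (!is.null(study$segments) && nrow(study$segments)) {
    utils::write.csv(study$segments, file.path(path, "segments.csv"),
                     row.names = FALSE)
  }
  if (!is.null(study$supplementary) && nrow(study$supplementary)) {
    utils::write.csv(study$supplementary, file.path(path, "supplementary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(study$ground_truth)) {
    jsonlite::write_json(study$ground_truth,
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.drm_study <- function(x, ...) {
  cat("Abbreviated-DRM study\n")
  cat(sprintf("  respondents : %d\n", nrow(x$respondents)))
  cat(sprintf("  episodes    : %d (%d test, %d retest)\n",
              nrow(x$episodes),
              sum(x$episodes$wave == "test"),
              sum(x$episodes$wave == "retest")))
  cat(sprintf("  segments    : %d (set D)\n", nrow(x$segments)))
  if (!is.null(x$supplementary)) {
    cat(sprintf("  supplementary answers: %d rows, %d items\n",
                nrow(x$supplementary), length(unique(x$supplementary$item))))
  }
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Set assignment of each respondent
#'
#' Derived from the test-wave records: sets A/B/C from episode records,
#' set D from segment records.
#'
#' @param study A `drm_study`.
#' @return Data frame with columns `respondent_id`, `set`.
#' @export
respondent_sets <- function(study) {
  ep <- study$episodes[study$episodes$wave == "test", c("respondent_id", "set")]
  ep <- unique(ep)
  sg <- unique(study$segments[study$segments$wave == "test", "respondent_id",
                              drop = FALSE])
  if (nrow(sg)) sg$set <- "D"
  out <- rbind(ep, sg)
  rownames(out) <- NULL
  out
}
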
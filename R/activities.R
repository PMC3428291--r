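#' Activity catalog of the abbreviated DRM
#'
#' The fixed 22-entry catalog of activity codes used by the day
#' reconstruction instrument.  Episodes may list more than one activity,
#' so per-activity reporting percentages can sum to more than 100.
#'
#' @return A data frame with columns `code` (machine-readable activity
#'   code) and `label` (human-readable description).
#' @export
#' @examples
#' drm_activities()
drm_activities <- function() {
  data.frame(
    code = c(
      "religious_activity", "reading", "exercising_leisurely_walk",
      "grooming_bathing", "watching_tv", "chatting", "working", "eating",
      "walking_somewhere", "rest", "housework", "preparing_food",
      "watching_children", "intimate_relations", "listening_radio",
      "other_leisure", "playing", "providing_care", "shopping",
      "subsistence_farming", "travel_bicycle", "travel_car_bus_train"
    ),
    label = c(
      "Religious activity", "Reading", "Exercising or leisurely walk",
      "Grooming or bathing (self)", "Watching TV", "Chatting with someone",
      "Working", "Eating", "Walking somewhere", "Rest", "Doing housework",
      "Preparing food", "Watching children", "Intimate relations/sex",
      "Listening to the radio", "Other leisurely activity", "Playing",
      "Providing care to someone", "Shopping", "Subsistence farming",
      "Travelling by bicycle", "Travelling by car/bus/train"
    ),
    stringsAsFactors = FALSE
  )
}

#' Companion catalog of the abbreviated DRM
#'
#' Codes for the "who were you with" question attached to each episode.
#' Companions are collected by the data model but not analysed by the
#' validation battery.
#'
#' @return Character vector of companion codes.
#' @export
drm_companions <- function() {
  c("alone", "spouse", "children", "other_family", "friends",
    "coworkers", "other")
}

# Split a semicolon-joined code field into a list of character vectors.
split_codes <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_codes <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

# Validate semicolon-joined activity fields against the catalog; `where`
# names the table for error messages.
check_activity_codes <- function(activities, where = "episodes") {
  codes <- split_codes(activities)
  known <- drm_activities()$code
  bad_rows <- which(vapply(
    codes,
    function(v) length(v) == 0L || any(!v %in% known),
    logical(1)
  ))
  if (length(bad_rows)) {
    stop(sprintf(
      "%s: unknown or empty activity code(s) in row(s) %s",
      where, paste(utils::head(bad_rows, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(codes)
}
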
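#' Cue delivery configuration
#'
#' Controls how level changes become user-facing cues: a short vibration on
#' every level change (increases and decreases alike), plus a feedback
#' message when the new level reaches `message_min_level` (default 3, i.e.
#' more than 2 SD above baseline). Cues can be gated on the wearer's
#' recognised activity: supply either `allowed_activities` (cues only
#' during these) or `blocked_activities` (cues suppressed during these),
#' never both. Gating suppresses cues only — measurements and level changes
#' stay in the event stream and timeline.
#'
#' @param message_min_level Lowest level at which the message fires
#'   (integer in `[-3, 5]`, default 3).
#' @param message_text Message shown at qualifying levels. The default is
#'   the stock text; set `personalized = TRUE` when supplying a user's own.
#' @param personalized Logical flag recording that `message_text` is
#'   user-defined rather than the default.
#' @param allowed_activities,blocked_activities Character vectors of
#'   activity labels; at most one may be non-`NULL`.
#' @param vibrate_on_change Emit a vibration cue on every level change
#'   (default `TRUE`).
#' @return A `cue_config` object.
#' @export
cue_config <- function(message_min_level = 3L,
                       message_text = "your heart rate is higher than average",
                       personalized = FALSE,
                       allowed_activities = NULL,
                       blocked_activities = NULL,
                       vibrate_on_change = TRUE) {
  if (!is.null(allowed_activities) && !is.null(blocked_activities)) {
    stop("supply allowed_activities or blocked_activities, not both",
         call. = FALSE)
  }
  stopifnot(message_min_level >= -3, message_min_level <= 5,
            is.character(message_text), nzchar(message_text))
  structure(list(
    message_min_level = as.integer(message_min_level),
    message_text = message_text,
    personalized = isTRUE(personalized),
    allowed_activities = allowed_activities,
    blocked_activities = blocked_activities,
    vibrate_on_change = isTRUE(vibrate_on_change)
  ), class = "cue_config")
}

#' Generate vibration and message cues from level events
#'
#' For every `level_change` event whose timestamp falls in a permitted
#' activity context, emits one vibration cue (if `vibrate_on_change`) and
#' additionally one message cue iff the new level is at least
#' `message_min_level`. A message fires on the transition into a qualifying
#' level — once per qualifying level change, not per sample while elevated.
#' Level changes in a gated activity context produce no cues but remain
#' untouched in the level stream.
#'
#' @param level_events Tibble from [process_stream()].
#' @param activity_intervals Optional [activity_stream()] for gating;
#'   `NULL` means no gating.
#' @param config A [cue_config()].
#' @return Tibble of cue events with columns `timestamp`, `kind`
#'   (`"vibration"` or `"message"`), `level`, `text` (empty for
#'   vibrations).
#' @examples
#' b <- calibrate(hr_stream(seq(0, by = 20, length.out = 200),
#'                          rep(70, 200), rep(TRUE, 200)))
#' s <- hr_stream(c(4000, 4020), c(71.5, 72.5), c(TRUE, TRUE))
#' generate_cues(process_stream(s, b))
#' @export
generate_cues <- function(level_events, activity_intervals = NULL,
                          config = cue_config()) {
  stopifnot(inherits(config, "cue_config"))
  changes <- level_events[level_events$kind == "level_change", , drop = FALSE]
  if (nrow(changes) == 0) return(empty_cue_events())

  permitted <- rep(TRUE, nrow(changes))
  if (!is.null(activity_intervals)) {
    lab <- activity_at(activity_intervals, changes$timestamp)
    if (!is.null(config$allowed_activities)) {
      permitted <- lab %in% config$allowed_activities
    } else if (!is.null(config$blocked_activities)) {
      permitted <- !(lab %in% config$blocked_activities)
    }
  }
  changes <- changes[permitted, , drop = FALSE]
  if (nrow(changes) == 0) return(empty_cue_events())

  ts <- numeric(0); kind <- character(0); lev <- integer(0); txt <- character(0)
  for (i in seq_len(nrow(changes))) {
    if (config$vibrate_on_change) {
      ts <- c(ts, changes$timestamp[i]); kind <- c(kind, "vibration")
      lev <- c(lev, changes$level[i]); txt <- c(txt, "")
    }
    if (changes$level[i] >= config$message_min_level) {
      ts <- c(ts, changes$timestamp[i]); kind <- c(kind, "message")
      lev <- c(lev, changes$level[i]); txt <- c(txt, config$message_text)
    }
  }
  tibble::tibble(timestamp = ts, kind = kind, level = lev, text = txt)
}

empty_cue_events <- function() {
  tibble::tibble(timestamp = numeric(), kind = character(),
                 level = integer(), text = character())
}
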
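#' Quantize heart rate into a discrete arousal level
#'
#' The arousal level is the discretized deviation of the current heart rate
#' from the personal baseline, in SD-wide bands, clamped to the integer
#' range -3..5. With `z = (bpm - mean_bpm) / sd_bpm`,
#'
#'   `level = clamp(ceiling(z), -3, 5)`
#'
#' so each interior level `k` corresponds to the half-open band
#' `z in (k-1, k]` (closed on the right: `z = 1` is level 1, `z = 2` is
#' level 2), `z > 4` clamps to 5 and `z <= -3` clamps to -3. A consequence
#' of this banding is that `level >= 3` exactly when `z > 2` — the
#' condition under which the feedback message is shown.
#'
#' @param bpm Numeric vector of heart rates in beats per minute.
#' @param baseline A `baseline_model` from [calibrate()].
#' @return Integer vector of levels in `[-3, 5]`.
#' @examples
#' b <- calibrate(hr_stream(seq(0, by = 20, length.out = 200),
#'                          rep(70, 200), rep(TRUE, 200)))
#' quantize(c(70, 81, 250, 20), b)
#' @export
quantize <- function(bpm, baseline) {
  stopifnot(inherits(baseline, "baseline_model"))
  if (!is.finite(baseline$sd_bpm) || baseline$sd_bpm <= 0) {
    stop("baseline SD must be positive; calibrate first", call. = FALSE)
  }
  z <- (bpm - baseline$mean_bpm) / baseline$sd_bpm
  as.integer(pmin(pmax(ceiling(z), -3), 5))
}

#' Run the level engine over a heart-rate stream
#'
#' Emits one `measurement` event per sample and a `level_change` event
#' whenever a reliable sample moves the quantized level away from the
#' current state. Unreliable samples are logged as measurements but never
#' update the level state, so sensor artifacts cannot drive cues. The level
#' state starts at 0 (at baseline).
#'
#' With a positive hysteresis margin `hysteresis_sd` (in baseline-SD
#' units), a change fires only once `z` has moved at least that margin
#' beyond the boundary of the current level's band — i.e. `z > L + h` to
#' leave level `L` upward, `z <= L - 1 - h` to leave it downward. At the
#' default `h = 0` this reduces to pure band crossing: the event sequence
#' equals per-sample re-quantization followed by change detection.
#'
#' @param samples An [hr_stream()].
#' @param baseline A `baseline_model`.
#' @param hysteresis_sd Non-negative hysteresis margin in SD units
#'   (default 0).
#' @return A tibble of level events with columns `timestamp`, `kind`
#'   (`"measurement"` or `"level_change"`), `bpm`, `z`, `level`,
#'   `previous_level` (`NA` for measurements), `reliable`. A `level_change`
#'   row always satisfies `level != previous_level`.
#' @export
process_stream <- function(samples, baseline, hysteresis_sd = 0) {
  stopifnot(inherits(baseline, "baseline_model"), hysteresis_sd >= 0)
  samples <- validate_hr_stream(samples)
  n <- nrow(samples)
  if (n == 0) return(empty_level_events())

  z_all <- (samples$bpm - baseline$mean_bpm) / baseline$sd_bpm
  q_all <- quantize(samples$bpm, baseline)

  # worst case: one measurement + one change per sample
  ts <- numeric(2 * n); kind <- character(2 * n); bpm <- numeric(2 * n)
  z <- numeric(2 * n); lev <- integer(2 * n); prev <- integer(2 * n)
  rel <- logical(2 * n)
  k <- 0L
  state <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    ts[k] <- samples$timestamp[i]; kind[k] <- "measurement"
    bpm[k] <- samples$bpm[i]; z[k] <- z_all[i]
    lev[k] <- state; prev[k] <- NA_integer_; rel[k] <- samples$reliable[i]
    if (!samples$reliable[i]) next
    if (q_all[i] != state) {
      crosses <- if (hysteresis_sd == 0) TRUE
      else if (q_all[i] > state) z_all[i] > state + hysteresis_sd
      else z_all[i] <= state - 1 - hysteresis_sd
      if (crosses) {
        k <- k + 1L
        ts[k] <- samples$timestamp[i]; kind[k] <- "level_change"
        bpm[k] <- samples$bpm[i]; z[k] <- z_all[i]
        lev[k] <- q_all[i]; prev[k] <- state; rel[k] <- TRUE
        state <- q_all[i]
      }
    }
  }
  idx <- seq_len(k)
  tibble::tibble(timestamp = ts[idx], kind = kind[idx], bpm = bpm[idx],
                 z = z[idx], level = lev[idx], previous_level = prev[idx],
                 reliable = rel[idx])
}

empty_level_events <- function() {
  tibble::tibble(timestamp = numeric(), kind = character(), bpm = numeric(),
                 z = numeric(), level = integer(),
                 previous_level = integer(), reliable = logical())
}

#' Write level/cue events as JSON lines
#'
#' One JSON object per line with keys `t`, `kind`, `bpm`, `z`, `level`,
#' `prev` (level events) or `t`, `kind`, `level`, `text` (cue events).
#'
#' @param events A tibble of level events ([process_stream()]) or cue
#'   events ([generate_cues()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    row <- as.list(events[i, , drop = FALSE])
    if ("timestamp" %in% names(row)) {
      names(row)[names(row) == "timestamp"] <- "t"
    }
    if ("previous_level" %in% names(row)) {
      names(row)[names(row) == "previous_level"] <- "prev"
    }
    row <- row[!vapply(row, function(v) length(v) == 1 && is.na(v), TRUE)]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
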
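#' Calibrate a personal heart-rate baseline
#'
#' The engine's reference frame is a personal baseline: the mean and
#' standard deviation of heart rate collected during a calibration window.
#' Calibration consumes the stream in time order and admits a sample iff it
#' is reliable, not inside an excluded-activity interval, and at least
#' `interval_s` seconds after the previously admitted sample (faster-than-
#' cadence input is thereby down-sampled). It completes at the moment the
#' `required_n`-th sample is admitted; samples arriving later never affect
#' the model.
#'
#' The summary uses the arithmetic mean and the sample standard deviation
#' (n-1 denominator) of the admitted samples. The SD is floored at
#' `sd_floor` so that a near-constant calibration stream cannot produce
#' degenerate, hypersensitive arousal bands; both the raw and floored SD
#' are retained.
#'
#' @param samples An [hr_stream()].
#' @param activity_intervals Optional [activity_stream()] used to exclude
#'   samples recorded during `excluded_activities`.
#' @param required_n Number of admitted samples needed to complete
#'   (default 200).
#' @param interval_s Minimum spacing in seconds between admitted samples
#'   (default 20).
#' @param excluded_activities Activity labels whose intervals are excluded
#'   from calibration (default `c("running", "cycling")`, a proxy for
#'   intense physical activity). Use `character()` to disable.
#' @param sd_floor Lower bound on the usable SD, in bpm (default 1).
#' @param preset Optional configuration preset overriding the defaults:
#'   `"evaluation"` (200 samples, activity exclusion on) or `"design"`
#'   (300 samples, no activity exclusion — calibration under unrestricted
#'   behaviour).
#' @return A `baseline_model` object: list with fields `mean_bpm`, `sd_bpm`
#'   (floored), `raw_sd_bpm`, `n_samples`, `interval_s`, `started_at`,
#'   `completed_at`, `excluded_activities`, `sd_floor`.
#' @examples
#' s <- hr_stream(seq(0, by = 20, length.out = 200),
#'                rep(70, 200), rep(TRUE, 200))
#' b <- calibrate(s)
#' b$mean_bpm   # 70
#' b$sd_bpm     # 1 (floored; raw SD is 0)
#' @export
calibrate <- function(samples, activity_intervals = NULL,
                      required_n = 200, interval_s = 20,
                      excluded_activities = c("running", "cycling"),
                      sd_floor = 1.0, preset = NULL) {
  if (!is.null(preset)) {
    p <- baseline_preset(preset)
    required_n <- p$required_n
    excluded_activities <- p$excluded_activities
    interval_s <- p$interval_s
  }
  stopifnot(required_n >= 2, interval_s > 0, sd_floor > 0)
  samples <- validate_hr_stream(samples)

  excluded <- rep(FALSE, nrow(samples))
  if (!is.null(activity_intervals) && length(excluded_activities) > 0) {
    excluded <- activity_at(activity_intervals, samples$timestamp) %in%
      excluded_activities
  }

  admitted_idx <- integer(0)
  last_t <- -Inf
  for (i in seq_len(nrow(samples))) {
    if (!samples$reliable[i] || excluded[i]) next
    if (samples$timestamp[i] - last_t < interval_s) next
    admitted_idx <- c(admitted_idx, i)
    last_t <- samples$timestamp[i]
    if (length(admitted_idx) == required_n) break
  }

  if (length(admitted_idx) < required_n) {
    stop("incomplete calibration: only ", length(admitted_idx), " of ",
         required_n, " required samples admitted", call. = FALSE)
  }

  v <- samples$bpm[admitted_idx]
  raw_sd <- stats::sd(v)
  model <- structure(list(
    mean_bpm = mean(v),
    sd_bpm = max(raw_sd, sd_floor),
    raw_sd_bpm = raw_sd,
    n_samples = length(v),
    interval_s = interval_s,
    started_at = samples$timestamp[admitted_idx[1]],
    completed_at = samples$timestamp[admitted_idx[length(admitted_idx)]],
    excluded_activities = as.character(excluded_activities),
    sd_floor = sd_floor
  ), class = "baseline_model")
  model
}

#' Baseline calibration presets
#'
#' Two deployment presets: `"evaluation"` calibrates on 200 reliable
#' samples at a 20-s cadence with intense activity (running, cycling)
#' excluded; `"design"` calibrates on 300 samples with no activity
#' exclusion, matching calibration under unrestricted everyday behaviour.
#'
#' @param name `"evaluation"` or `"design"`.
#' @return List with `required_n`, `interval_s`, `excluded_activities`.
#' @export
baseline_preset <- function(name = c("evaluation", "design")) {
  name <- match.arg(name)
  switch(name,
    evaluation = list(required_n = 200L, interval_s = 20,
                      excluded_activities = c("running", "cycling")),
    design = list(required_n = 300L, interval_s = 20,
                  excluded_activities = character(0))
  )
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Personal heart-rate baseline\n")
  cat(sprintf("  mean: %.2f bpm   SD: %.2f bpm (raw %.3f, floor %.1f)\n",
              x$mean_bpm, x$sd_bpm, x$raw_sd_bpm, x$sd_floor))
  cat(sprintf("  %d samples at >=%g s spacing, completed %s\n",
              x$n_samples, x$interval_s, format_iso8601(x$completed_at)))
  if (length(x$excluded_activities) > 0) {
    cat("  excluded activities:",
        paste(x$excluded_activities, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a baseline model to / from JSON
#'
#' @param model A `baseline_model`.
#' @param path File path for the JSON document.
#' @return `write_baseline()` returns `path` invisibly; `read_baseline()`
#'   returns a `baseline_model`.
#' @export
write_baseline <- function(model, path) {
  stopifnot(inherits(model, "baseline_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$excluded_activities <- as.character(x$excluded_activities)
  structure(x, class = "baseline_model")
}
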
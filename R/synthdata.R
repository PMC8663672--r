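#' Configure a synthetic wearable heart-rate scenario
#'
#' The simulator emulates the statistical structure the biocueing engine
#' assumes in wrist-PPG heart-rate data: a personal baseline with Gaussian
#' sample-to-sample variability, a flat circadian dip during a nighttime
#' window (deep enough, at the defaults, to push readings below 50 bpm and
#' exercise the usage filter), additive elevations during scheduled
#' physical activity, transient arousal episodes with trapezoidal (linear
#' ramp) profiles whose amplitude is expressed in baseline-SD units, and
#' independent per-sample dropout to unreliable readings. It makes no
#' attempt at beat-to-beat HRV or autocorrelated noise: the engine consumes
#' only mean and SD, so an i.i.d. Gaussian around a piecewise-deterministic
#' mean is the simplest structure that exercises every code path.
#'
#' @param seed Integer RNG seed; the same (seed, config) pair reproduces
#'   the scenario exactly.
#' @param duration_h Scenario length in hours.
#' @param cadence_s Sampling cadence in seconds (default 20, the wearable's
#'   measurement interval).
#' @param start_time Epoch seconds of the first sample (default 0,
#'   i.e. local midnight at a zero timezone offset).
#' @param tz_offset_min Local-clock offset from UTC in minutes, used only
#'   to place the night window.
#' @param baseline_mean_bpm,baseline_sd_bpm Resting heart-rate mean and SD
#'   (defaults 70 and 5 bpm, typical wrist-PPG resting values).
#' @param circadian_dip_bpm Flat reduction applied during the night window
#'   (default 25 bpm, yielding nighttime readings near 45 bpm).
#' @param night_window Local clock hours `c(from, to)` of the dip
#'   (default `c(0, 6)`).
#' @param activity_schedule Optional [activity_stream()] of scheduled
#'   activity bouts.
#' @param activity_elevation_bpm Named numeric vector of additive bpm
#'   elevations per activity label.
#' @param episodes Data frame of arousal episodes with columns `onset`
#'   (epoch seconds), `duration_s` (total, including both ramps),
#'   `amplitude_sd` (peak, in baseline-SD units), `ramp_s` (linear
#'   ramp-up/-down time).
#' @param unreliable_prob Per-sample probability of an unreliable reading
#'   (default 0.05).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L, duration_h = 24, cadence_s = 20,
                            start_time = 0, tz_offset_min = 0,
                            baseline_mean_bpm = 70, baseline_sd_bpm = 5,
                            circadian_dip_bpm = 25,
                            night_window = c(0, 6),
                            activity_schedule = NULL,
                            activity_elevation_bpm = c(
                              still = 0, walking = 15, running = 50,
                              cycling = 40, in_vehicle = 0, unknown = 0),
                            episodes = NULL,
                            unreliable_prob = 0.05) {
  stopifnot(duration_h > 0, cadence_s > 0,
            unreliable_prob >= 0, unreliable_prob <= 1,
            baseline_sd_bpm >= 0,
            length(night_window) == 2)
  if (!is.null(episodes)) {
    stopifnot(all(c("onset", "duration_s", "amplitude_sd", "ramp_s") %in%
                    names(episodes)),
              all(episodes$duration_s > 0),
              all(episodes$duration_s >= 2 * episodes$ramp_s),
              all(episodes$ramp_s >= 0))
  }
  structure(list(
    seed = as.integer(seed), duration_h = duration_h, cadence_s = cadence_s,
    start_time = start_time, tz_offset_min = tz_offset_min,
    baseline_mean_bpm = baseline_mean_bpm,
    baseline_sd_bpm = baseline_sd_bpm,
    circadian_dip_bpm = circadian_dip_bpm,
    night_window = night_window,
    activity_schedule = activity_schedule,
    activity_elevation_bpm = activity_elevation_bpm,
    episodes = episodes,
    unreliable_prob = unreliable_prob
  ), class = "scenario_config")
}

# trapezoidal episode profile in [0, 1]: linear ramp up over ramp_s,
# plateau, linear ramp down over ramp_s; duration_s spans the whole shape
trapezoid <- function(t, onset, duration_s, ramp_s) {
  offset <- onset + duration_s
  up_end <- onset + ramp_s
  down_start <- offset - ramp_s
  out <- numeric(length(t))
  if (ramp_s > 0) {
    ru <- t >= onset & t < up_end
    out[ru] <- (t[ru] - onset) / ramp_s
    rd <- t > down_start & t < offset
    out[rd] <- (offset - t[rd]) / ramp_s
  }
  out[t >= up_end & t <= down_start] <- 1
  out
}

is_night <- function(t, tz_offset_min, night_window) {
  tod_h <- ((t + tz_offset_min * 60) %% 86400) / 3600
  from <- night_window[1]; to <- night_window[2]
  if (from <= to) tod_h >= from & tod_h < to
  else tod_h >= from | tod_h < to   # window wrapping midnight
}

#' Simulate a wearable heart-rate scenario with ground truth
#'
#' Generates the heart-rate trace
#' `HR(t) = baseline_mean + circadian(t) + activity(t) + episode(t) + e`,
#' `e ~ N(0, baseline_sd)`, sampled at the configured cadence, together
#' with the activity-interval stream and a ground-truth record of the true
#' signal components. Each sample is flagged unreliable independently with
#' probability `unreliable_prob`. Heart rate is floored at 1 bpm. The
#' output is a deterministic function of (seed, config).
#'
#' @param config A [scenario_config()].
#' @return A list with elements `hr` (an [hr_stream()]), `activity` (an
#'   [activity_stream()], possibly empty) and `truth` (a
#'   `scenario_ground_truth` list: `episodes` tibble with `onset`,
#'   `offset`, `peak_amplitude_sd`; `night_intervals`; per-sample
#'   `components` tibble; and `duration_h`).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- floor(config$duration_h * 3600 / config$cadence_s)
  t <- config$start_time + config$cadence_s * (seq_len(n) - 1)

  night <- is_night(t, config$tz_offset_min, config$night_window)
  circadian <- ifelse(night, -config$circadian_dip_bpm, 0)

  activity <- numeric(n)
  act <- config$activity_schedule
  if (!is.null(act) && nrow(act) > 0) {
    lab <- activity_at(act, t)
    elev <- config$activity_elevation_bpm
    known <- lab %in% names(elev)
    activity[known] <- unname(elev[lab[known]])
  } else {
    act <- activity_stream()
  }

  episode <- numeric(n)
  eps <- config$episodes
  if (!is.null(eps) && nrow(eps) > 0) {
    for (i in seq_len(nrow(eps))) {
      episode <- episode + eps$amplitude_sd[i] * config$baseline_sd_bpm *
        trapezoid(t, eps$onset[i], eps$duration_s[i], eps$ramp_s[i])
    }
  }

  noise <- stats::rnorm(n, 0, config$baseline_sd_bpm)
  bpm <- pmax(config$baseline_mean_bpm + circadian + activity + episode +
                noise, 1)
  reliable <- stats::runif(n) >= config$unreliable_prob

  truth_eps <- if (!is.null(eps) && nrow(eps) > 0) {
    tibble::tibble(onset = eps$onset,
                   offset = eps$onset + eps$duration_s,
                   peak_amplitude_sd = eps$amplitude_sd)
  } else {
    tibble::tibble(onset = numeric(), offset = numeric(),
                   peak_amplitude_sd = numeric())
  }
  # contiguous night runs as intervals
  r <- rle(night)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values
  night_iv <- tibble::tibble(start = t[starts[keep]],
                             end = t[ends[keep]] + config$cadence_s)

  truth <- structure(list(
    episodes = truth_eps,
    night_intervals = night_iv,
    components = tibble::tibble(timestamp = t, circadian = circadian,
                                activity = activity, episode = episode,
                                noise = noise, night = night),
    duration_h = config$duration_h
  ), class = "scenario_ground_truth")

  list(hr = hr_stream(t, bpm, reliable), activity = act, truth = truth)
}

#' Cue detection performance against simulator ground truth
#'
#' An episode counts as detected when any message cue falls inside
#' `[onset - w, offset + w]` for match window `w`; sensitivity is the
#' detected fraction. Message cues matching no episode are false alerts,
#' reported per simulated hour. Vibration cues are ignored: only the
#' elevated-arousal message is an alert in this sense.
#'
#' @param cue_events Tibble from [generate_cues()].
#' @param truth A `scenario_ground_truth` from [simulate_scenario()].
#' @param match_window_s Positive match window in seconds.
#' @return List with `sensitivity` (fraction in `[0, 1]`, or `NA` when the
#'   scenario has no episodes), `false_alerts_per_hour`, `n_detected`,
#'   `n_episodes`, `n_false_alerts`.
#' @export
detection_metrics <- function(cue_events, truth, match_window_s) {
  stopifnot(inherits(truth, "scenario_ground_truth"), match_window_s > 0)
  msgs <- cue_events$timestamp[cue_events$kind == "message"]
  eps <- truth$episodes
  n_eps <- nrow(eps)

  detected <- logical(n_eps)
  matched <- rep(FALSE, length(msgs))
  for (i in seq_len(n_eps)) {
    hit <- msgs >= eps$onset[i] - match_window_s &
      msgs <= eps$offset[i] + match_window_s
    detected[i] <- any(hit)
    matched <- matched | hit
  }
  list(
    sensitivity = if (n_eps == 0) NA_real_ else sum(detected) / n_eps,
    false_alerts_per_hour = sum(!matched) / truth$duration_h,
    n_detected = sum(detected),
    n_episodes = n_eps,
    n_false_alerts = sum(!matched)
  )
}
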
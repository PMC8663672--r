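test_that("the simulator is deterministic in (seed, config)", {
  cfg <- scenario_config(seed = 77, duration_h = 2)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$hr, b$hr)
  expect_identical(a$truth$components, b$truth$components)
  # a different seed changes the trace
  c <- simulate_scenario(scenario_config(seed = 78, duration_h = 2))
  expect_false(identical(a$hr$bpm, c$hr$bpm))
})

test_that("a zero-variability scenario yields a constant trace and no level changes", {
  cfg <- scenario_config(seed = 1, duration_h = 3, baseline_sd_bpm = 0,
                         circadian_dip_bpm = 0, unreliable_prob = 0,
                         start_time = 8 * 3600)
  sim <- simulate_scenario(cfg)
  expect_true(all(sim$hr$bpm == 70))
  b <- calibrate(sim$hr)   # SD floors to 1
  ev <- process_stream(sim$hr, b)
  expect_equal(sum(ev$kind == "level_change"), 0)
})

test_that("ground truth mirrors the configured episodes and night window", {
  eps <- data.frame(onset = c(30000, 40000, 50000),
                    duration_s = c(600, 300, 900),
                    amplitude_sd = c(3, 4, 5), ramp_s = c(60, 0, 120))
  cfg <- scenario_config(seed = 2, duration_h = 24, episodes = eps)
  sim <- simulate_scenario(cfg)
  expect_equal(nrow(sim$truth$episodes), 3)
  expect_equal(sim$truth$episodes$offset, eps$onset + eps$duration_s)
  expect_equal(sim$truth$episodes$peak_amplitude_sd, eps$amplitude_sd)
  # night flag covers exactly local 00:00-06:00 at zero offset
  night_hours <- (sim$truth$components$timestamp %% 86400) / 3600
  expect_equal(sim$truth$components$night, night_hours < 6)
})

test_that("episode profiles are trapezoids with the configured ramps", {
  t <- seq(0, 1000, by = 10)
  y <- biocue:::trapezoid(t, onset = 200, duration_s = 400, ramp_s = 100)
  expect_equal(y[t <= 200], rep(0, sum(t <= 200)))
  expect_equal(y[t == 250], 0.5)
  expect_equal(y[t >= 300 & t <= 500], rep(1, sum(t >= 300 & t <= 500)))
  expect_equal(y[t == 550], 0.5)
  expect_equal(y[t >= 600], rep(0, sum(t >= 600)))
})

test_that("the quiescent daytime portion recovers the configured mean", {
  cfg <- scenario_config(seed = 123, duration_h = 3, start_time = 9 * 3600,
                         unreliable_prob = 0)
  sim <- simulate_scenario(cfg)
  se <- 5 / sqrt(nrow(sim$hr))
  expect_lt(abs(mean(sim$hr$bpm) - 70), 3 * se)
})

test_that("unreliable dropout hits roughly the configured rate", {
  cfg <- scenario_config(seed = 8, duration_h = 24, unreliable_prob = 0.2)
  sim <- simulate_scenario(cfg)
  p_hat <- mean(!sim$hr$reliable)
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(sim$hr)))
})

test_that("detection metrics agree with an exhaustive pairing oracle", {
  truth_of <- function(onset, offset, dur_h) {
    structure(list(
      episodes = tibble::tibble(onset = onset, offset = offset,
                                peak_amplitude_sd = rep(4, length(onset))),
      night_intervals = tibble::tibble(start = numeric(), end = numeric()),
      components = tibble::tibble(), duration_h = dur_h),
      class = "scenario_ground_truth")
  }
  cues_of <- function(t) {
    tibble::tibble(timestamp = t, kind = rep("message", length(t)),
                   level = rep(3L, length(t)), text = "x")
  }

  # perfect coverage, no extras
  m <- detection_metrics(cues_of(c(100, 600)),
                         truth_of(c(50, 550), c(200, 700), 1), 60)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$false_alerts_per_hour, 0)

  # no cues at all
  m0 <- detection_metrics(cues_of(numeric(0)),
                          truth_of(100, 200, 1), 60)
  expect_equal(m0$sensitivity, 0)

  # zero-episode scenario: sensitivity not applicable
  mna <- detection_metrics(cues_of(100), truth_of(numeric(0), numeric(0), 2),
                           60)
  expect_true(is.na(mna$sensitivity))
  expect_equal(mna$false_alerts_per_hour, 0.5)

  # random sets vs brute-force pairing
  for (seed in 1:15) {
    set.seed(seed)
    n_ep <- sample(1:5, 1); n_cue <- sample(0:10, 1)
    onset <- sort(runif(n_ep, 0, 7000))
    offset <- onset + runif(n_ep, 50, 400)
    cues_t <- sort(runif(n_cue, 0, 7200))
    w <- 100
    m <- detection_metrics(cues_of(cues_t), truth_of(onset, offset, 2), w)
    det <- vapply(seq_len(n_ep), function(i) {
      any(cues_t >= onset[i] - w & cues_t <= offset[i] + w)
    }, logical(1))
    fa <- vapply(cues_t, function(ct) {
      !any(ct >= onset - w & ct <= offset + w)
    }, logical(1))
    expect_equal(m$sensitivity, mean(det))
    expect_equal(m$false_alerts_per_hour, sum(fa) / 2)
  }
})

test_that("scenario CSV/JSON outputs round-trip through the stream readers", {
  cfg <- scenario_config(seed = 3, duration_h = 1,
                         activity_schedule = activity_stream(
                           600, 1200, "walking"))
  sim <- simulate_scenario(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_hr_stream(sim$hr, f)
  back <- read_hr_stream(f)
  expect_equal(back$reliable, sim$hr$reliable)
  expect_equal(back$bpm, sim$hr$bpm, tolerance = 1e-8)
  # walking bout raises mean heart rate in that window
  in_walk <- sim$hr$timestamp >= 600 & sim$hr$timestamp < 1200
  expect_gt(mean(sim$hr$bpm[in_walk]), mean(sim$hr$bpm[!in_walk]) + 5)
})
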
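---
title: "The biocue engine: baseline calibration, arousal levels, cues, and evaluation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biocue engine: baseline calibration, arousal levels, cues, and evaluation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocue)
```

## The problem

Biocueing is ambulatory biofeedback: a wearable measures a physiological
correlate of arousal — here, wrist-PPG heart rate sampled every 20 seconds —
and cues the wearer in real time when their arousal deviates from their own
baseline, so that self-regulation can start before behavioural escalation.
The clinically interesting case is slowly rising arousal that the wearer
does not notice. `biocue` is a device-independent implementation of such an
engine: everything from the raw heart-rate stream to the cue, the event
timeline, the adherence metric, and the instrument scoring used to evaluate
such a system, runnable end to end on synthetic data with ground truth.

## The model

### Personal baseline

The reference frame is personal: `calibrate()` consumes a heart-rate stream
in time order and admits a sample iff it is (i) flagged reliable, (ii) not
inside an excluded-activity interval, and (iii) at least `interval_s`
(default 20 s) after the previously admitted sample. Calibration completes
at the `required_n`-th admitted sample — 200 in the default (`"evaluation"`)
preset, 300 in the `"design"` preset, which also disables activity
exclusion because that deployment calibrated under unrestricted behaviour.
The model is the arithmetic mean and the sample standard deviation (n − 1
denominator; an unbiased choice from a finite window) of the admitted
samples.

Two deliberate conventions where the field leaves room:

* **Admit-then-space.** The cadence rule is evaluated against the last
  *admitted* sample, which down-samples faster-than-cadence input rather
  than rejecting it.
* **SD floor.** `sd_bpm = max(raw_sd, 1)` bpm. A constant calibration
  stream would otherwise make the quantizer divide by zero, and a
  near-constant one would make 1-SD bands absurdly narrow. The floor bounds
  the engine's sensitivity; the raw SD is kept alongside for inspection.

Reliability itself is an engine convention, since consumer wearables flag
confidence without documenting a criterion: `mark_reliability()` defines a
sample as reliable iff the sensor flag is set *and* the reading lies in a
plausibility window (default 30–220 bpm).

### Arousal levels

`quantize()` maps a reading to a discrete arousal level via
`z = (bpm − mean)/sd` and

```
level = clamp(ceiling(z), −3, 5)
```

Each interior level `k` owns the half-open band `z ∈ (k−1, k]`; boundaries
belong to the lower level (`z = 2` is level 2, anything above is level 3).
This is the unique uniform 1-SD banding on −3..5 under which *level ≥ 3 ⇔
z > 2*, i.e. the feedback message fires exactly when heart rate exceeds the
baseline by more than 2 SD. `process_stream()` emits a measurement event
per sample and a level-change event whenever a **reliable** sample's
quantized level differs from the current state; unreliable samples are
logged but can never move the state, so sensor artifacts cannot cue the
user. The state starts at 0 (at baseline).

An optional hysteresis margin `h` (SD units, default 0) requires `z` to
move at least `h` beyond the current level's band boundary (`z > L + h`
upward, `z ≤ L − 1 − h` downward) before a change fires. At `h = 0` this
reduces exactly to band crossing; the margin exists because users of such
systems find boundary chatter — and the resulting notification volume —
burdensome.

### Cues

`generate_cues()` turns level changes into user-facing cues: one vibration
per level change (decreases included — every change is informative), plus a
message when the new level reaches `message_min_level` (default 3, default
text "your heart rate is higher than average", replaceable by a
personalized message). A message fires on the *transition into* a
qualifying level, never per sample while elevated. Activity gating
(either an allowed-list or a blocked-list of activity labels, not both)
suppresses cues — e.g. while driving — but deliberately leaves measurement
and level events in the stream: the timeline keeps its full record either
way, and both the "pause operation" and the "filter notifications" reading
of activity profiles are expressible in config.

### Timeline, usage, instruments

The timeline is an append-only record of events with user annotations: a
free-text note and a subjective arousal rating, fixed at integers 0–10
following subjective-units-of-distress practice. JSONL export is lossless;
CSV export flattens.

`usage_hours()` computes the adherence indicator: measurement count × the
20-s nominal cadence, corrected by excluding readings below 50 bpm
(typically sleep or a device measuring while not worn) and samples whose
*local* clock time falls in the half-open nighttime window [00:00, 06:00).
Count-times-cadence is used instead of summing inter-sample gaps because
the indicator is defined as a number of measurements; gap heuristics would
smuggle in wear-time assumptions. A nighttime low-HR sample is booked once,
as a night exclusion — precedence affects only the bookkeeping split.

The scales module scores the evaluation instruments. `sus_score()` is the
standard System Usability Scale formula (odd items `r − 1`, even items
`5 − r`, total × 2.5, range 0–100, no proration). Likert instruments
(AQ-SF, STAXI-2, ABSQ) are scored as item means on the native response
scale, with reverse-keyed reflection and proration when at least 80% of a
(sub)scale's items are answered — a common psychometric convention. The
shipped item-to-subscale mappings are consecutive-block placeholders:
these instruments are copyrighted and their item keys are not
redistributable, so real analyses must supply the licensed mapping via
`scale_config()` or a JSON/YAML file.

`wilcoxon_matched_pairs()` is the pre/post test: zeros dropped by default
(Pratt's zero-rank method by flag), average ranks for ties, `W` the
smaller rank sum. The two-sided p is **exact** — the full null
distribution of the positive rank sum, built by convolution over the
ranks, equivalent to enumerating all 2^n sign assignments — whenever at
most 15 nonzero differences remain; beyond that a normal approximation is
used with continuity correction and the exact rank-sum variance
`Var(W⁺) = Σrᵢ²/4` (which subsumes the textbook tie correction). `Z`
carries the sign of `W⁺ − W⁻`. `pearson_r()` reports the product-moment
correlation with the t-transform p on n − 2 degrees of freedom (Spearman
by flag, since association analyses on such small evaluation samples are
sometimes rank-based).

## The simulator

`simulate_scenario()` generates what the engine assumes:

```
HR(t) = baseline_mean + circadian(t) + activity(t) + episode(t) + ε,
ε ~ N(0, baseline_sd)
```

sampled at the cadence, with independent per-sample dropout to unreliable
readings. Defaults are chosen as typical resting wrist-PPG values: mean 70
bpm, SD 5 bpm, 20-s cadence, 5% dropout. The circadian term is a flat
−25 bpm inside the local 00:00–06:00 window — deliberately crude, but deep
enough to push readings below 50 bpm and exercise the usage filter.
Activity bouts add a per-label elevation (e.g. +15 walking, +50 running).
Arousal episodes are trapezoids: linear ramps of `ramp_s` seconds around a
plateau, with peak amplitude expressed in baseline-SD units, so tests can
distinguish slow- from fast-onset arousal. Identical (seed, config) yields
identical output.

What the simulator does **not** model: autocorrelated heart-rate dynamics,
heart-rate variability, circadian transitions, correlated dropout bursts,
or accelerometer signals (activity labels are generated directly). The
engine consumes only a mean and an SD, so i.i.d. Gaussian noise around a
piecewise-deterministic mean exercises every code path; but passing tests
on this synthetic structure demonstrate the *engine's* correctness, not
detection performance on real, autocorrelated wrist data, where effective
sample sizes are smaller and artifacts are not independent.

`detection_metrics()` scores cue performance against ground truth: an
episode is detected if any *message* cue (vibrations are not alerts in
this sense) falls within the episode extended by a match window; message
cues matching no episode are false alerts per simulated hour. With the
default 1-SD noise, quiescent z exceeds 2 on roughly 2% of samples, so a
nonzero false-alert rate is the expected behaviour of a 2-SD threshold
engine, not a defect.

## Numerical and testing choices

* Timestamps are UTC epoch seconds throughout; local-clock rules enter
  only via a configured timezone offset.
* Band boundaries are right-closed; quantization at an exact boundary is
  deterministic, not tie-broken.
* CSV round trips are byte-stable: numeric output uses a fixed 10
  significant-digit format that re-parses to the value that produced it.
* The exact Wilcoxon null is computed on the doubled-rank integer grid so
  average ranks (halves) stay exact.
* Test problem sizes are kept small and seeded — e.g. 50 calibration
  recovery runs of 2-hour scenarios, and 20 seeds × 3 amplitudes of
  3.5-hour scenarios for the detection property — sizes at which every
  property is already decisive while the whole suite runs in seconds.
* Degenerate inputs have defined behaviour rather than errors where a
  value is meaningful: an empty stream yields empty events; an
  all-zero-difference Wilcoxon yields p = 1 flagged degenerate; a
  zero-episode scenario reports sensitivity as NA, not 0.

## Worked example

```{r example}
# simulate a day, calibrate, run the engine, and score it
eps <- data.frame(onset = 10 * 3600 + c(1800, 14400),
                  duration_s = 600, amplitude_sd = 4, ramp_s = 60)
cfg <- scenario_config(seed = 11, duration_h = 10, start_time = 8 * 3600,
                       unreliable_prob = 0.02, episodes = eps)
sim <- simulate_scenario(cfg)

bl <- calibrate(sim$hr)
bl

events <- process_stream(sim$hr, bl)
cues <- generate_cues(events)
detection_metrics(cues, sim$truth, match_window_s = 600)

usage_hours(sim$hr)
```

## Known limitations

* The engine is single-signal (heart rate); no fusion with skin
  conductance or respiration.
* The reliability criterion and the hysteresis semantics are engine
  conventions where deployed devices leave the behaviour undocumented.
* Instrument scoring ships placeholder item mappings; clinical use
  requires the licensed keys.
* Adherence hours cannot distinguish a worn device at rest from an unworn
  device that still measures; the low-HR/night correction is a coarse
  proxy, not wear detection.
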
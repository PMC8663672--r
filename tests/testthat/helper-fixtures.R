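# Shared fixture builders. Everything is generated in code; no stored data.

# regular-cadence stream, optionally with a reliability mask
make_stream <- function(bpm, cadence = 20, start = 0, reliable = NULL) {
  n <- length(bpm)
  if (is.null(reliable)) reliable <- rep(TRUE, n)
  hr_stream(start + cadence * (seq_len(n) - 1), bpm, reliable)
}

# a completed constant-70 baseline (mean 70, SD floored to 1)
constant_baseline <- function(mean_bpm = 70, n = 200) {
  calibrate(make_stream(rep(mean_bpm, n)))
}

# seeded Gaussian stream around a mean
gaussian_stream <- function(n, mean = 65, sd = 6, cadence = 20, seed = 1,
                            start = 0) {
  set.seed(seed)
  make_stream(stats::rnorm(n, mean, sd), cadence = cadence, start = start)
}

# independent linear-scan oracle for activity lookup
activity_at_oracle <- function(intervals, t) {
  vapply(t, function(ti) {
    for (i in seq_len(nrow(intervals))) {
      if (ti >= intervals$start[i] && ti < intervals$end[i]) {
        return(intervals$label[i])
      }
    }
    "unknown"
  }, character(1))
}

# independent re-quantization + change-detection oracle for process_stream
level_change_oracle <- function(samples, baseline) {
  state <- 0L
  out <- integer(0)
  for (i in seq_len(nrow(samples))) {
    if (!samples$reliable[i]) next
    q <- quantize(samples$bpm[i], baseline)
    if (q != state) {
      out <- c(out, q)
      state <- q
    }
  }
  out
}

# brute-force two-sided exact signed-rank p over all 2^n sign vectors
wilcoxon_enumeration_oracle <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w <- min(w_plus, sum(r) - w_plus)
  all_wplus <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  total <- sum(r)
  min(1, mean(all_wplus <= w + 1e-9) + mean(all_wplus >= total - w - 1e-9))
}

# SUS formula written out independently of sus_score
sus_oracle <- function(resp) {
  s <- 0
  for (i in 1:10) {
    s <- s + if (i %% 2 == 1) resp[i] - 1 else 5 - resp[i]
  }
  s * 2.5
}
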
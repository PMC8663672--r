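#' Construct a heart-rate sample stream
#'
#' A heart-rate stream is the atomic input of the biocueing engine: an
#' ordered sequence of timestamped beats-per-minute readings, each carrying
#' a sensor-confidence (reliability) flag. Timestamps are stored as seconds
#' since the Unix epoch in UTC; any local-clock logic (e.g. the nighttime
#' window of the usage metric) is applied downstream via a configured
#' timezone offset, never baked into the samples.
#'
#' @param timestamp Numeric vector, seconds since epoch (UTC). Must be
#'   strictly increasing.
#' @param bpm Numeric vector of heart rates in beats per minute. Must be
#'   positive wherever `reliable` is `TRUE`.
#' @param reliable Logical vector; the wearable's per-sample confidence flag.
#' @return A tibble of class `hr_stream` with columns `timestamp`, `bpm`,
#'   `reliable`.
#' @examples
#' hr_stream(timestamp = c(0, 20, 40), bpm = c(70, 72, 71),
#'           reliable = c(TRUE, TRUE, FALSE))
#' @export
hr_stream <- function(timestamp = numeric(), bpm = numeric(),
                      reliable = logical()) {
  stopifnot(length(timestamp) == length(bpm),
            length(timestamp) == length(reliable))
  x <- tibble::tibble(
    timestamp = as.numeric(timestamp),
    bpm = as.numeric(bpm),
    reliable = as.logical(reliable)
  )
  class(x) <- c("hr_stream", class(x))
  validate_hr_stream(x)
}

#' @rdname hr_stream
#' @param x An object to validate as a heart-rate stream.
#' @export
validate_hr_stream <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("timestamp", "bpm", "reliable") %in% names(x)))
  if (nrow(x) > 1) {
    bad <- which(diff(x$timestamp) <= 0)
    if (length(bad) > 0) {
      stop("hr_stream timestamps must be strictly increasing; first ",
           "violation at row ", bad[1] + 1L, call. = FALSE)
    }
  }
  bad_bpm <- which(x$reliable & !(x$bpm > 0))
  if (length(bad_bpm) > 0) {
    stop("reliable samples must have bpm > 0; first violation at row ",
         bad_bpm[1], call. = FALSE)
  }
  x
}

#' Construct an activity-interval stream
#'
#' Activity intervals are labelled time spans produced by an external
#' activity-recognition pipeline (consumed here as input, never derived
#' from raw accelerometry). They gate cue delivery and can exclude samples
#' from baseline calibration. Intervals within one stream may not overlap;
#' overlaps are rejected rather than merged so that ambiguity surfaces.
#' Intervals are half-open `[start, end)`.
#'
#' @param start,end Numeric vectors, seconds since epoch (UTC), `start < end`.
#' @param label Character vector; one of `r paste(activity_labels(), collapse = ", ")`.
#' @return A tibble of class `activity_stream` with columns `start`, `end`,
#'   `label`, sorted by `start`.
#' @export
activity_stream <- function(start = numeric(), end = numeric(),
                            label = character()) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  x <- tibble::tibble(start = as.numeric(start), end = as.numeric(end),
                      label = as.character(label))
  x <- x[order(x$start), , drop = FALSE]
  class(x) <- c("activity_stream", class(x))
  validate_activity_stream(x)
}

#' Recognised activity labels
#' @return Character vector of valid activity-recognition labels.
#' @export
activity_labels <- function() {
  c("still", "walking", "running", "cycling", "in_vehicle", "unknown")
}

#' @rdname activity_stream
#' @param x An object to validate as an activity stream.
#' @export
validate_activity_stream <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("start", "end", "label") %in% names(x)))
  bad_lab <- setdiff(unique(x$label), activity_labels())
  if (length(bad_lab) > 0) {
    stop("unknown activity label(s): ", paste(bad_lab, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$start >= x$end)) {
    stop("activity intervals require start < end", call. = FALSE)
  }
  if (nrow(x) > 1) {
    o <- order(x$start)
    s <- x$start[o]; e <- x$end[o]
    if (any(s[-1] < e[-length(e)])) {
      stop("activity intervals overlap; overlapping intervals are rejected, ",
           "not merged", call. = FALSE)
    }
  }
  x
}

# ISO-8601 <-> epoch seconds. The engine's canonical time axis is UTC;
# files carry "YYYY-mm-ddTHH:MM:SSZ".
parse_iso8601 <- function(x) {
  t <- as.POSIXct(sub("Z$", "", x), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  as.numeric(t)
}

format_iso8601 <- function(t) {
  format(as.POSIXct(round(t), origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

fmt_num <- function(x) {
  # deterministic, re-parse-stable numeric formatting for canonical CSVs
  sprintf("%.10g", x)
}

#' Read and write heart-rate stream CSV files
#'
#' The on-disk format is a plain CSV with header
#' `timestamp_iso,bpm,reliable`: ISO-8601 UTC timestamps, beats per minute,
#' and the reliability flag coded 0/1. Reading validates the stream
#' invariants (strictly increasing timestamps, positive bpm on reliable
#' samples) and reports the first offending line; writing then reading a
#' stream is the identity on content, and re-writing a file produced by
#' [write_hr_stream()] reproduces it byte for byte.
#'
#' @param path Path to a CSV file.
#' @return `read_hr_stream()` returns an [hr_stream()]; `write_hr_stream()`
#'   returns `path` invisibly.
#' @export
read_hr_stream <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_iso", "bpm", "reliable")
  if (!all(need %in% names(d))) {
    stop("expected columns ", paste(need, collapse = ","), " in ", path,
         call. = FALSE)
  }
  ts <- parse_iso8601(d$timestamp_iso)
  bad <- which(is.na(ts) | is.na(suppressWarnings(as.numeric(d$bpm))))
  if (length(bad) > 0) {
    stop("unparseable row at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  if (nrow(d) > 1) {
    mono <- which(diff(ts) <= 0)
    if (length(mono) > 0) {
      stop("non-monotone timestamps at line ", mono[1] + 2L, " of ", path,
           call. = FALSE)
    }
  }
  hr_stream(timestamp = ts, bpm = as.numeric(d$bpm),
            reliable = as.integer(d$reliable) != 0L)
}

#' @rdname read_hr_stream
#' @param samples An [hr_stream()].
#' @export
write_hr_stream <- function(samples, path) {
  samples <- validate_hr_stream(samples)
  lines <- c("timestamp_iso,bpm,reliable",
             paste(format_iso8601(samples$timestamp),
                   fmt_num(samples$bpm),
                   as.integer(samples$reliable), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write activity-interval CSV files
#'
#' Format: header `start_iso,end_iso,label` with ISO-8601 UTC timestamps
#' and an activity-recognition label per row. Overlapping intervals are
#' rejected at load.
#'
#' @param path Path to a CSV file.
#' @return `read_activity_stream()` returns an [activity_stream()];
#'   `write_activity_stream()` returns `path` invisibly.
#' @export
read_activity_stream <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_iso", "end_iso", "label")
  if (!all(need %in% names(d))) {
    stop("expected columns ", paste(need, collapse = ","), " in ", path,
         call. = FALSE)
  }
  activity_stream(start = parse_iso8601(d$start_iso),
                  end = parse_iso8601(d$end_iso),
                  label = d$label)
}

#' @rdname read_activity_stream
#' @param intervals An [activity_stream()].
#' @export
write_activity_stream <- function(intervals, path) {
  intervals <- validate_activity_stream(intervals)
  lines <- c("start_iso,end_iso,label",
             paste(format_iso8601(intervals$start),
                   format_iso8601(intervals$end),
                   intervals$label, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Re-flag sample reliability with a physiological plausibility window
#'
#' Wrist PPG sensors emit a per-sample confidence flag but no documented
#' criterion; this engine defines a sample as reliable when the sensor flag
#' is set AND the reading lies inside a physiological plausibility window
#' (default 30-220 bpm), which guards against motion artifacts that slip
#' past the sensor's own flag. The operation is idempotent.
#'
#' @param samples An [hr_stream()].
#' @param min_bpm,max_bpm Plausibility window bounds in bpm
#'   (`min_bpm < max_bpm`); a sample outside `[min_bpm, max_bpm]` is
#'   re-flagged unreliable.
#' @return The stream with `reliable` recomputed as
#'   `original flag & bpm in [min_bpm, max_bpm]`.
#' @examples
#' s <- hr_stream(c(0, 20), c(70, 25), c(TRUE, TRUE))
#' mark_reliability(s)$reliable  # TRUE FALSE
#' @export
mark_reliability <- function(samples, min_bpm = 30, max_bpm = 220) {
  stopifnot(min_bpm < max_bpm)
  samples <- validate_hr_stream(samples)
  samples$reliable <- samples$reliable &
    samples$bpm >= min_bpm & samples$bpm <= max_bpm
  samples
}

#' Activity label covering a time point
#'
#' Looks up the activity interval covering each query time; times falling
#' in a gap between intervals (or outside all of them) report `"unknown"`.
#' Intervals are half-open `[start, end)`.
#'
#' @param intervals An [activity_stream()].
#' @param t Numeric vector of query timestamps (seconds since epoch).
#' @return Character vector of labels, one per element of `t`.
#' @export
activity_at <- function(intervals, t) {
  intervals <- validate_activity_stream(intervals)
  out <- rep("unknown", length(t))
  if (nrow(intervals) == 0 || length(t) == 0) return(out)
  # intervals are sorted and non-overlapping: findInterval on starts
  o <- order(intervals$start)
  s <- intervals$start[o]; e <- intervals$end[o]; lab <- intervals$label[o]
  idx <- findInterval(t, s)
  hit <- idx >= 1 & ifelse(idx >= 1, t < e[pmax(idx, 1)], FALSE)
  out[hit] <- lab[idx[hit]]
  out
}
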
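#' Event timeline with annotations and subjective arousal reports
#'
#' The timeline persists measurement, level-change and cue events in
#' arrival order and lets the user attach a free-text note and a
#' subjective arousal rating (integer 0-10, after subjective-units-of-
#' distress practice) to any entry. Annotation never alters the underlying
#' event payload, its timestamp or the ordering; storage is an append-only
#' structure exported losslessly to JSON lines.
#'
#' @return `timeline()` returns an empty `biocue_timeline` tibble with
#'   columns `entry_id`, `timestamp`, `kind`, `bpm`, `z`, `level`,
#'   `previous_level`, `text`, `note`, `subjective_arousal`.
#' @export
timeline <- function() {
  x <- tibble::tibble(
    entry_id = integer(), timestamp = numeric(), kind = character(),
    bpm = numeric(), z = numeric(), level = integer(),
    previous_level = integer(), text = character(),
    note = character(), subjective_arousal = integer()
  )
  class(x) <- c("biocue_timeline", class(x))
  x
}

#' Append events to a timeline
#'
#' Events must not move backwards in time relative to the last entry; a
#' time regression is an error. Each appended entry receives a fresh
#' sequential `entry_id`.
#'
#' @param tl A [timeline()].
#' @param events A tibble of level events ([process_stream()]) or cue
#'   events ([generate_cues()]), or any tibble with at least `timestamp`
#'   and `kind` columns.
#' @return The extended timeline.
#' @export
timeline_append <- function(tl, events) {
  stopifnot(inherits(tl, "biocue_timeline"))
  if (nrow(events) == 0) return(tl)
  if (!all(c("timestamp", "kind") %in% names(events))) {
    stop("events need timestamp and kind columns", call. = FALSE)
  }
  last_t <- if (nrow(tl) > 0) tl$timestamp[nrow(tl)] else -Inf
  if (events$timestamp[1] < last_t ||
      (nrow(events) > 1 && any(diff(events$timestamp) < 0))) {
    stop("time regression: events must not predate the last timeline entry",
         call. = FALSE)
  }
  next_id <- if (nrow(tl) > 0) max(tl$entry_id) + 1L else 1L
  col_or_na <- function(nm, proto) {
    if (nm %in% names(events)) events[[nm]] else rep(proto, nrow(events))
  }
  new <- tibble::tibble(
    entry_id = seq.int(next_id, length.out = nrow(events)),
    timestamp = events$timestamp,
    kind = events$kind,
    bpm = as.numeric(col_or_na("bpm", NA_real_)),
    z = as.numeric(col_or_na("z", NA_real_)),
    level = as.integer(col_or_na("level", NA_integer_)),
    previous_level = as.integer(col_or_na("previous_level", NA_integer_)),
    text = as.character(col_or_na("text", NA_character_)),
    note = rep(NA_character_, nrow(events)),
    subjective_arousal = rep(NA_integer_, nrow(events))
  )
  out <- rbind(tl, new)
  class(out) <- class(tl)
  out
}

#' Annotate a timeline entry
#'
#' Attaches a free-text note and/or a subjective arousal rating to an
#' existing entry. Re-annotation overwrites the previous values.
#'
#' @param tl A [timeline()].
#' @param entry_id Id of an existing entry.
#' @param note Free text, or `NULL` to leave unchanged.
#' @param subjective_arousal Integer in `[0, 10]`, or `NULL` to leave
#'   unchanged.
#' @return The updated timeline.
#' @export
annotate <- function(tl, entry_id, note = NULL, subjective_arousal = NULL) {
  stopifnot(inherits(tl, "biocue_timeline"))
  i <- match(entry_id, tl$entry_id)
  if (is.na(i)) stop("no timeline entry with id ", entry_id, call. = FALSE)
  if (!is.null(subjective_arousal)) {
    if (subjective_arousal != round(subjective_arousal) ||
        subjective_arousal < 0 || subjective_arousal > 10) {
      stop("subjective_arousal must be an integer in [0, 10]", call. = FALSE)
    }
    tl$subjective_arousal[i] <- as.integer(subjective_arousal)
  }
  if (!is.null(note)) tl$note[i] <- as.character(note)
  tl
}

#' Export and import a timeline
#'
#' `export_timeline()` writes JSON lines (`format = "jsonl"`; lossless —
#' re-import reproduces the timeline exactly) or a flattened CSV
#' (`format = "csv"` with columns
#' `t,kind,bpm,z,level,prev,cue_text,note,subjective_arousal`).
#' `import_timeline()` reads the JSONL form back.
#'
#' @param tl A [timeline()].
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `export_timeline()` returns `path` invisibly;
#'   `import_timeline()` returns a `biocue_timeline`.
#' @export
export_timeline <- function(tl, path, format = c("jsonl", "csv")) {
  stopifnot(inherits(tl, "biocue_timeline"))
  format <- match.arg(format)
  if (format == "jsonl") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(tl))) {
      row <- lapply(as.list(tl[i, , drop = FALSE]), function(v) v[[1]])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"), con)
    }
  } else {
    d <- data.frame(t = tl$timestamp, kind = tl$kind, bpm = tl$bpm,
                    z = tl$z, level = tl$level, prev = tl$previous_level,
                    cue_text = tl$text, note = tl$note,
                    subjective_arousal = tl$subjective_arousal)
    utils::write.csv(d, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname export_timeline
#' @export
import_timeline <- function(path) {
  lines <- readLines(path)
  tl <- timeline()
  if (length(lines) == 0) return(tl)
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  get <- function(nm, cast, na) {
    cast(unlist(lapply(rows, function(r) {
      v <- r[[nm]]
      if (is.null(v) || length(v) == 0) na else v
    })))
  }
  out <- tibble::tibble(
    entry_id = get("entry_id", as.integer, NA_integer_),
    timestamp = get("timestamp", as.numeric, NA_real_),
    kind = get("kind", as.character, NA_character_),
    bpm = get("bpm", as.numeric, NA_real_),
    z = get("z", as.numeric, NA_real_),
    level = get("level", as.integer, NA_integer_),
    previous_level = get("previous_level", as.integer, NA_integer_),
    text = get("text", as.character, NA_character_),
    note = get("note", as.character, NA_character_),
    subjective_arousal = get("subjective_arousal", as.integer, NA_integer_)
  )
  class(out) <- class(tl)
  out
}
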
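# Keypress event tables: reading, session segmentation, daily aggregation.
#
# An event table is a plain data.frame with columns
#   subject_id, session_id, timestamp_utc (ISO-8601, seconds precision),
#   timezone (IANA zone name), category (one of KEY_CATEGORIES).
# The keyboard logger records only metadata -- category and timing -- never
# typed content, so this is the complete per-event schema.

KEY_CATEGORIES <- c("alphanumeric", "backspace", "autocorrection",
                    "punctuation", "autosuggestion", "special")

EVENT_COLUMNS <- c("subject_id", "session_id", "timestamp_utc", "timezone",
                   "category")

# Parse ISO-8601 UTC timestamps ("2024-05-01T13:00:05", space separator and a
# trailing Z also accepted). Returns POSIXct (UTC) with NA for unparseable.
parse_utc <- function(x) {
  x <- sub("Z$", "", sub("T", " ", as.character(x)))
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
}

validate_events <- function(events, file = NULL) {
  miss <- setdiff(EVENT_COLUMNS, names(events))
  if (length(miss) > 0)
    stop_keymix("event table is missing column(s): %s", toString(miss))
  where <- if (is.null(file)) "row" else paste0(file, " row")
  bad_cat <- which(!(events$category %in% KEY_CATEGORIES))
  if (length(bad_cat) > 0)
    stop_keymix("unknown key category %s at %s %s (valid: %s)",
                dQuote(events$category[bad_cat[1]]), where, bad_cat[1],
                toString(KEY_CATEGORIES))
  tm <- parse_utc(events$timestamp_utc)
  bad_tm <- which(is.na(tm))
  if (length(bad_tm) > 0)
    stop_keymix("unparseable timestamp %s at %s %s (expected ISO-8601)",
                dQuote(as.character(events$timestamp_utc[bad_tm[1]])),
                where, bad_tm[1])
  bad_tz <- which(!(events$timezone %in% OlsonNames()))
  if (length(bad_tz) > 0)
    stop_keymix("unknown IANA timezone %s at %s %s",
                dQuote(events$timezone[bad_tz[1]]), where, bad_tz[1])
  invisible(events)
}

#' Read keypress metadata events
#'
#' Reads a keystroke metadata export into the package's event table. Columns:
#' `subject_id`, `session_id`, `timestamp_utc` (ISO-8601, seconds precision),
#' `timezone` (IANA name, e.g. `"America/Chicago"`), `category` (one of
#' alphanumeric, backspace, autocorrection, punctuation, autosuggestion,
#' special). Every row is validated; the first offending row is named in the
#' error message.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"` (one JSON object per line).
#' @return a data.frame of validated events, one row per keypress.
#' @seealso [segment_sessions()], [aggregate_daily()]
#' @export
read_keystroke_events <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  events <- switch(format,
    csv = utils::read.csv(path, colClasses = "character"),
    jsonl = jsonlite::stream_in(file(path), verbose = FALSE)
  )
  events <- as.data.frame(lapply(events, as.character),
                          stringsAsFactors = FALSE)
  validate_events(events, file = path)
  events
}

#' Segment keypress events into typing sessions
#'
#' A typing session ends after more than `gap_seconds` of keyboard inactivity
#' (the logger's rule is 6 seconds), so consecutive events separated by a gap
#' strictly greater than the threshold fall into different sessions; a gap of
#' exactly `gap_seconds` stays within the session. Events are sorted by
#' timestamp within subject (stable, so duplicate timestamps keep their input
#' order) and every event is assigned to exactly one session.
#'
#' @param events event table (see [read_keystroke_events()]); may contain
#'   several subjects, which are segmented independently.
#' @param gap_seconds inactivity threshold in seconds (default 6).
#' @return the event table, sorted by subject and time, with an added integer
#'   column `session_index` numbering sessions within subject.
#' @export
segment_sessions <- function(events, gap_seconds = 6) {
  validate_events(events)
  stopifnot(is.numeric(gap_seconds), gap_seconds >= 0)
  tm <- as.numeric(parse_utc(events$timestamp_utc))
  ord <- order(events$subject_id, tm)  # stable: ties keep input order
  events <- events[ord, , drop = FALSE]
  tm <- tm[ord]
  new_subject <- c(TRUE, events$subject_id[-1] != events$subject_id[-nrow(events)])
  gap <- c(0, diff(tm))
  new_session <- new_subject | gap > gap_seconds
  idx <- stats::ave(as.integer(new_session), events$subject_id,
                    FUN = cumsum)
  events$session_index <- idx
  rownames(events) <- NULL
  events
}

#' Aggregate keypress events into daily backspace rates
#'
#' The daily backspace rate is the number of backspace keypresses on a local
#' calendar day divided by the total number of keypresses that day (backspaces
#' included in the denominator). Days are delimited at local midnight in each
#' event's recorded timezone -- typing behaviour is diurnal, so the calendar
#' day a user experienced is the right unit, not the UTC day. Days with fewer
#' than `min_keypresses` events are dropped entirely (never emitted as 0/0).
#'
#' @param events validated event table.
#' @param min_keypresses minimum events for a subject-day to be retained
#'   (default 1).
#' @param denominator key categories counted as keypresses; defaults to all
#'   six. `"backspace"` must be included.
#' @return a data.frame with one row per retained subject-day: `subject_id`,
#'   `date` (`YYYY-MM-DD`, local), `n_keypresses`, `n_backspaces`, `rate`.
#' @export
aggregate_daily <- function(events, min_keypresses = 1,
                            denominator = KEY_CATEGORIES) {
  validate_events(events)
  stopifnot(min_keypresses >= 1)
  if (!("backspace" %in% denominator))
    stop_keymix("the denominator categories must include \"backspace\"")
  keep <- events$category %in% denominator
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0)
    return(data.frame(subject_id = character(), date = character(),
                      n_keypresses = integer(), n_backspaces = integer(),
                      rate = numeric()))
  tm <- parse_utc(events$timestamp_utc)
  local_date <- character(nrow(events))
  for (tz in unique(events$timezone)) {
    i <- events$timezone == tz
    local_date[i] <- format(tm[i], "%Y-%m-%d", tz = tz)
  }
  key <- paste(events$subject_id, local_date, sep = "\r")
  n_key <- tapply(rep_len(1L, nrow(events)), key, sum)
  n_bsp <- tapply(events$category == "backspace", key, sum)
  parts <- do.call(rbind, strsplit(names(n_key), "\r", fixed = TRUE))
  out <- data.frame(subject_id = parts[, 1], date = parts[, 2],
                    n_keypresses = as.integer(n_key),
                    n_backspaces = as.integer(n_bsp),
                    stringsAsFactors = FALSE)
  out <- out[out$n_keypresses >= min_keypresses, , drop = FALSE]
  out$rate <- out$n_backspaces / out$n_keypresses
  out <- out[order(out$subject_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write and read daily backspace-rate tables
#'
#' Plain CSV with columns `subject_id`, `date`, `n_keypresses`,
#' `n_backspaces`, `rate`; `read_daily_rates` validates the count and bound
#' invariants so a written table round-trips unchanged.
#'
#' @param rates daily rate table as produced by [aggregate_daily()].
#' @param path file path.
#' @return `read_daily_rates` returns the validated data.frame;
#'   `write_daily_rates` is called for its side effect.
#' @export
write_daily_rates <- function(rates, path) {
  stopifnot(all(c("subject_id", "date", "n_keypresses", "n_backspaces",
                  "rate") %in% names(rates)))
  utils::write.csv(rates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_rates
#' @export
read_daily_rates <- function(path) {
  out <- utils::read.csv(path, colClasses = c(subject_id = "character",
                                              date = "character"))
  need <- c("subject_id", "date", "n_keypresses", "n_backspaces", "rate")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0)
    stop_keymix("daily rate table is missing column(s): %s", toString(miss))
  bad <- which(out$n_backspaces > out$n_keypresses | out$n_keypresses < 1 |
                 out$rate < 0 | out$rate > 1)
  if (length(bad) > 0)
    stop_keymix("invalid daily rate record at %s row %s", path, bad[1])
  out
}
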
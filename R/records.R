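# Raw-record and contact-interval containers plus their JSON readers and
# writers.
#
# One record is a 5-element JSON array:
#   ["pr014", "pr037", "datetime(2023,4,25,7,39,43)", 74, 0]
#   (a) reporting badge  (b) detected badge  (c) start time of contact
#   (d) sensed distance in inches  (e) duration in seconds
# In raw data a zero duration marks the start of a contact and a nonzero
# duration marks its end; even end records carry the START time of the
# interval. In contact-interval files the duration is never zero.
# Files may be xz-compressed (.xz suffix).

new_records <- function(reporter = character(), detected = character(),
                        start_time = .POSIXct(numeric(), tz = .TZ),
                        distance_in = integer(), duration_s = integer(),
                        class2 = "raw_records") {
  df <- data.frame(reporter = as.character(reporter),
                   detected = as.character(detected),
                   start_time = as_badge_time(start_time),
                   distance_in = as.integer(distance_in),
                   duration_s = as.integer(duration_s),
                   stringsAsFactors = FALSE)
  class(df) <- c(class2, "data.frame")
  df
}

#' Build a table of raw badge records
#'
#' @param reporter,detected badge labels.
#' @param start_time `POSIXct` (or `datetime(...)` strings); for end-of-
#'   interval records this is still the START time of the interval.
#' @param distance_in sensed distance in inches (non-negative integers).
#' @param duration_s 0 for a start-of-contact record, the elapsed contact
#'   duration in seconds for an end record.
#' @return data frame of class `raw_records`.
#' @export
raw_records <- function(reporter = character(), detected = character(),
                        start_time = .POSIXct(numeric(), tz = .TZ),
                        distance_in = integer(), duration_s = integer()) {
  df <- new_records(reporter, detected, start_time, distance_in, duration_s)
  validate_records(df, intervals = FALSE)
  df
}

#' Build a table of contact intervals
#'
#' A contact interval is a reconstructed period of continuous sub-threshold
#' proximity between two badges; its duration is always positive (matched
#' intervals are multiples of the 15-second badge processing cycle,
#' unmatched ones carry the 10-second substitute).
#'
#' @inheritParams raw_records
#' @param duration_s positive interval durations in seconds.
#' @return data frame of class `contact_intervals`.
#' @export
contact_intervals <- function(reporter = character(), detected = character(),
                              start_time = .POSIXct(numeric(), tz = .TZ),
                              distance_in = integer(), duration_s = integer()) {
  df <- new_records(reporter, detected, start_time, distance_in, duration_s,
                    class2 = "contact_intervals")
  validate_records(df, intervals = TRUE)
  df
}

validate_records <- function(df, intervals = FALSE) {
  if (nrow(df) == 0) return(invisible(df))
  ok <- is_valid_badge(df$reporter) & is_valid_badge(df$detected)
  if (!all(ok)) {
    stop("invalid badge label(s) at record(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  if (any(df$distance_in < 0L)) stop("negative sensed distance", call. = FALSE)
  if (any(df$duration_s < 0L)) stop("negative duration", call. = FALSE)
  if (intervals && any(df$duration_s == 0L)) {
    stop("contact intervals must have positive duration (got duration 0 at record(s) ",
         paste(utils::head(which(df$duration_s == 0L), 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(df)
}

is_xz_path <- function(path) grepl("\\.xz$", path, ignore.case = TRUE)

read_text_maybe_xz <- function(path, compressed = NULL) {
  compressed <- compressed %||% is_xz_path(path)
  con <- if (compressed) xzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  paste(readLines(con, warn = FALSE), collapse = "\n")
}

write_text_maybe_xz <- function(txt, path, compressed = NULL) {
  compressed <- compressed %||% is_xz_path(path)
  con <- if (compressed) xzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Read raw badge records or contact intervals from JSON
#'
#' Reads a JSON array of 5-field records (the common format of raw data
#' and contact-interval files), optionally xz-compressed. Records are
#' returned in file order; the published files are *not* guaranteed to be
#' sorted.
#'
#' @param path file path, or a single string of JSON text via `text =`.
#' @param compressed logical; `NULL` (default) auto-detects from the
#'   `.xz` suffix.
#' @param intervals logical; if `TRUE` validate as contact intervals
#'   (positive durations) and return a `contact_intervals` table.
#' @param lenient logical; if `TRUE`, malformed records are skipped with a
#'   log line instead of raising an error.
#' @param text JSON text to parse instead of a file.
#' @param quiet suppress log lines.
#' @return a `raw_records` or `contact_intervals` data frame.
#' @export
#' @examples
#' parse_raw_records(text = '[["pr014","pr037","datetime(2023,4,25,7,39,43)",74,0]]')
parse_raw_records <- function(path = NULL, compressed = NULL, intervals = FALSE,
                              lenient = FALSE, text = NULL, quiet = FALSE) {
  txt <- if (is.null(text)) read_text_maybe_xz(path, compressed) else text
  arr <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.list(arr)) stop("expected a JSON array of records", call. = FALSE)
  cls <- if (intervals) "contact_intervals" else "raw_records"
  if (length(arr) == 0) return(new_records(class2 = cls))
  bad <- integer()
  note <- function(i, ...) {
    why <- paste0(...)
    if (lenient) {
      mt_log("record ", i, " skipped: ", why, quiet = quiet)
      bad <<- c(bad, i)
    } else stop("record ", i, ": ", why, call. = FALSE)
  }
  n <- length(arr)
  rep_ <- det <- tim <- character(n)
  dst <- dur <- integer(n)
  for (i in seq_len(n)) {
    r <- arr[[i]]
    if (length(r) != 5L) { note(i, "expected 5 fields, got ", length(r)); next }
    rp <- as.character(r[[1]]); dt <- as.character(r[[2]])
    if (!is_valid_badge(rp) || !is_valid_badge(dt)) {
      note(i, sprintf("unknown badge prefix in '%s' / '%s'", rp, dt)); next
    }
    tt <- tryCatch(parse_badge_datetime(as.character(r[[3]])), error = function(e) NULL)
    if (is.null(tt)) { note(i, sprintf("unparseable datetime '%s'", as.character(r[[3]]))); next }
    d4 <- suppressWarnings(as.integer(r[[4]]))
    d5 <- suppressWarnings(as.integer(r[[5]]))
    if (is.na(d4) || is.na(d5)) { note(i, "non-numeric distance or duration"); next }
    rep_[i] <- rp; det[i] <- dt; tim[i] <- format_badge_datetime(tt)
    dst[i] <- d4; dur[i] <- d5
  }
  keep <- setdiff(seq_len(n), bad)
  df <- new_records(rep_[keep], det[keep], parse_badge_datetime(tim[keep]),
                    dst[keep], dur[keep], class2 = cls)
  validate_records(df, intervals = intervals)
  df
}

#' @rdname parse_raw_records
#' @export
read_intervals <- function(path, compressed = NULL, quiet = FALSE) {
  parse_raw_records(path, compressed = compressed, intervals = TRUE, quiet = quiet)
}

#' Write raw records or contact intervals as JSON
#'
#' Emits the exact 5-field array layout of the raw-data/interval format,
#' one record per line inside a JSON array, xz-compressed when requested
#' (or when the path ends in `.xz`). `parse_raw_records()` after
#' `write_records()` is the identity.
#'
#' @param records a `raw_records` or `contact_intervals` data frame.
#' @param path output file path.
#' @param compressed logical; `NULL` auto-detects from the `.xz` suffix.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path, compressed = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(write_text_maybe_xz("[]", path, compressed))
  body <- sprintf('["%s", "%s", "%s", %d, %d]',
                  records$reporter, records$detected,
                  format_badge_datetime(records$start_time),
                  as.integer(records$distance_in), as.integer(records$duration_s))
  txt <- paste0("[\n", paste(body, collapse = ",\n"), "\n]")
  write_text_maybe_xz(txt, path, compressed)
}
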
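# From raw records to contact intervals.
#
# Stages, composed by build_intervals():
#   1. filter_min_distance(): drop records sensed at less than 12 inches
#      (badges powered on together in a receptacle at shift handout or
#      turn-in produce such records; worn badges cannot be that close).
#   2. pair_start_end(): match each start record (duration 0) to its end
#      record (same reporter, detectee, and start time; end records carry
#      the START time). Matched pairs give the end record's duration (a
#      multiple of the 15-second badge processing cycle); a start with no
#      end -- the badge system effectively ignores contacts shorter than
#      15 s -- becomes a 10-second substitute interval.
#   3. merge_bidirectional(): badge clocks drift by some seconds, so the
#      (a,b) and (b,a) views of one contact can disagree; overlapping
#      intervals of a pair are rewritten to the common [min start, max end]
#      span, to a fixpoint, and every span is mirrored in both directions.
# Interval spans are half-open [start, start + duration).

#' Drop raw records sensed at implausibly short distances
#'
#' Records with a sensed distance below 12 inches are skipped: they arise
#' from badges lying together in a receptacle around shift handout and
#' turn-in, not from worn badges. The bound is exclusive, so a distance of
#' exactly `min_in` is kept. Order is preserved.
#'
#' @param records a `raw_records` data frame.
#' @param min_in minimum retained distance in inches (default 12).
#' @return filtered `raw_records`.
#' @export
filter_min_distance <- function(records, min_in = 12L) {
  records[records$distance_in >= min_in, , drop = FALSE]
}

#' Match start and end records into contact intervals
#'
#' Start records (duration 0) are matched to end records on the exact key
#' (reporter, detected, start time); end records carry the start time of
#' their interval. Matched pairs yield the end record's duration. A start
#' with no matching end yields a 10-second substitute interval. Orphan end
#' records (no start) are retained as intervals of their stated duration
#' and logged; exact duplicate records are deduplicated with a log line;
#' if several end records share a key the largest duration wins.
#'
#' @param records distance-filtered `raw_records`.
#' @param unmatched_s substitute duration for unmatched starts (default 10).
#' @param quiet suppress log lines.
#' @return `contact_intervals`, sorted by start time then (reporter,
#'   detected).
#' @export
pair_start_end <- function(records, unmatched_s = 10L, quiet = FALSE) {
  if (nrow(records) == 0) {
    return(new_records(class2 = "contact_intervals"))
  }
  dt <- as.data.table(unclass2(records))
  ndup <- nrow(dt)
  dt <- unique(dt)
  if (nrow(dt) < ndup) {
    mt_log("deduplicated ", ndup - nrow(dt), " identical raw record(s)", quiet = quiet)
  }
  key <- c("reporter", "detected", "start_time")
  starts <- dt[duration_s == 0L]
  ends <- dt[duration_s > 0L]
  if (nrow(starts) > 0) {
    setorderv(starts, c(key, "distance_in"))
    extra <- duplicated(starts, by = key)
    if (any(extra)) {
      mt_log("dropped ", sum(extra), " duplicate start record(s) sharing a key",
             quiet = quiet)
      starts <- starts[!extra]
    }
  }
  # several ends sharing a key: keep the largest duration
  if (nrow(ends) > 0) {
    setorderv(ends, c(key, "duration_s"), order = c(1L, 1L, 1L, -1L))
    extra <- duplicated(ends, by = key)
    if (any(extra)) {
      mt_log("dropped ", sum(extra), " shorter duplicate end record(s) sharing a start key",
             quiet = quiet)
      ends <- ends[!extra]
    }
  }
  merged <- merge(starts[, c(key, "distance_in"), with = FALSE],
                  ends, by = key, all = TRUE, suffixes = c("", ".end"))
  orphan_end <- is.na(merged$distance_in)       # end with no start
  unmatched <- is.na(merged$duration_s)         # start with no end
  if (any(orphan_end)) {
    mt_log(sum(orphan_end), " end record(s) with no matching start retained as intervals",
           quiet = quiet)
    merged$distance_in[orphan_end] <- merged$distance_in.end[orphan_end]
  }
  merged$duration_s[unmatched] <- as.integer(unmatched_s)
  out <- new_records(merged$reporter, merged$detected, merged$start_time,
                     merged$distance_in, merged$duration_s,
                     class2 = "contact_intervals")
  out <- out[order(out$start_time, out$reporter, out$detected), , drop = FALSE]
  rownames(out) <- NULL
  validate_records(out, intervals = TRUE)
  out
}

# strip the records class so data.table conversion is clean
unclass2 <- function(df) { class(df) <- "data.frame"; df }

#' Union overlapping bidirectional contact intervals
#'
#' The (a,b) and (b,a) views of one physical contact can disagree by some
#' seconds because badge clocks drift between synchronising scans. Any
#' interval for a pair overlapping in time (optionally within `slack_s`)
#' an interval for the reversed pair is rewritten so that both span the
#' minimum start to the maximum end; rewriting is repeated to a fixpoint
#' so chained overlaps coalesce. Every resulting span is present in both
#' directions (mirror completeness); a span with no counterpart gets a
#' mirrored copy. The distance of a merged interval is the minimum
#' (closest approach) of its constituents.
#'
#' @param intervals a `contact_intervals` data frame.
#' @param slack_s extra seconds within which disjoint spans still merge
#'   (default 0: strict overlap of half-open spans).
#' @return merged `contact_intervals`, mirror-complete, sorted by start
#'   time then (reporter, detected).
#' @export
merge_bidirectional <- function(intervals, slack_s = 0L) {
  if (nrow(intervals) == 0) return(intervals)
  s <- as.numeric(intervals$start_time)
  e <- s + intervals$duration_s
  a <- pmin(intervals$reporter, intervals$detected)
  b <- pmax(intervals$reporter, intervals$detected)
  dt <- data.table(a = a, b = b, s = s, e = e, d = as.integer(intervals$distance_in))
  setorder(dt, a, b, s, e)
  # Within each unordered pair, a scanline coalesces spans whose half-open
  # extents (widened by slack) intersect: break a group when the next start
  # is at or past the running maximum end plus slack. This is the
  # transitive closure of the pairwise rewrite rule once mirrored copies
  # exist, so one pass reaches the fixpoint.
  dt[, gid := {
    prev_max <- shift(cummax(e), fill = -Inf)
    cumsum(s >= prev_max + slack_s)
  }, by = .(a, b)]
  out <- dt[, .(s = min(s), e = max(e), d = min(d)), by = .(a, b, gid)]
  res <- rbind(
    data.frame(reporter = out$a, detected = out$b, s = out$s, e = out$e, d = out$d),
    data.frame(reporter = out$b, detected = out$a, s = out$s, e = out$e, d = out$d))
  res <- res[order(res$s, res$reporter, res$detected), , drop = FALSE]
  fin <- new_records(res$reporter, res$detected, .POSIXct(res$s, tz = .TZ),
                     res$d, as.integer(res$e - res$s),
                     class2 = "contact_intervals")
  rownames(fin) <- NULL
  fin
}

#' Build contact intervals from raw records
#'
#' Composition of [filter_min_distance()], [pair_start_end()] and
#' [merge_bidirectional()]; deterministic for a fixed input.
#'
#' @inheritParams filter_min_distance
#' @inheritParams pair_start_end
#' @inheritParams merge_bidirectional
#' @param merge union bidirectional intervals (default `TRUE`); set
#'   `FALSE` to inspect the directed intervals as matched.
#' @return `contact_intervals`.
#' @export
build_intervals <- function(records, min_in = 12L, unmatched_s = 10L,
                            slack_s = 0L, merge = TRUE, quiet = FALSE) {
  iv <- pair_start_end(filter_min_distance(records, min_in = min_in),
                       unmatched_s = unmatched_s, quiet = quiet)
  if (merge) iv <- merge_bidirectional(iv, slack_s = slack_s)
  iv
}
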
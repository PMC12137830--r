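# History file format: a JSON object keyed by datetime strings; each value
# maps HCP badge labels to {"contacts": [...], "state": null | {"room": r,
# "inroom": true/false}}. Files may be xz-compressed. Seconds with no
# entries may be omitted (the writer omits them; the reader accepts both
# sparse and dense files).

#' Write an imputed history as JSON
#'
#' Entries are emitted in time order; within a second, badges in label
#' order and contacts ordered by first-contact time then label. Seconds
#' with no contacts are omitted. The writer assembles the JSON by
#' vectorised string operations because dense per-second histories grow to
#' hundreds of thousands of keys.
#'
#' @param history a `badge_history`.
#' @param path output path; `.xz` suffix triggers compression.
#' @param compressed logical; `NULL` auto-detects from the suffix.
#' @return the path, invisibly.
#' @export
write_history <- function(history, path, compressed = NULL) {
  cr <- history$contacts
  ann <- is_annotated(history)
  st <- if (ann) history$state else empty_state_runs()
  if (nrow(cr) == 0 && nrow(st) == 0) {
    return(write_text_maybe_xz("{}", path, compressed))
  }
  dt <- data.table(badge = cr$badge, contact = cr$contact,
                   s = as.numeric(cr$start), e = as.numeric(cr$end))
  dt[, rid := .I]
  long <- dt[, .(t = seq.int(s, e - 1)), by = .(rid, badge, contact, s)]
  setorder(long, t, badge, s, contact)
  stq <- data.table(badge = st$badge, s = as.numeric(st$start),
                    e = as.numeric(st$end), room = st$room)
  # one JSON fragment per (t, badge)
  per_badge <- long[, .(contacts = paste0('"', contact, '"', collapse = ",")),
                    by = .(t, badge)]
  if (nrow(stq) > 0) {
    # a badge can hold an in-room state while touching nothing; such
    # seconds still get an entry (with an empty contacts list), so the
    # state survives serialisation
    stq[, rid := .I]
    st_long <- stq[, .(t = seq.int(s, e - 1)), by = .(rid, badge)]
    extra <- st_long[!per_badge, on = .(t, badge), .(t, badge, contacts = "")]
    if (nrow(extra)) {
      per_badge <- rbind(per_badge, extra)
      setorder(per_badge, t, badge)
    }
  }
  if (nrow(stq) > 0) {
    setkey(stq, badge, s, e)
    idx <- stq[per_badge, on = .(badge, s <= t, e > t), which = TRUE, mult = "first"]
    room <- stq$room[idx]
  } else {
    room <- rep(NA_integer_, nrow(per_badge))
  }
  state_txt <- ifelse(is.na(room), "null",
                      sprintf('{"room": %d, "inroom": true}', room))
  per_badge[, frag := sprintf('"%s": {"contacts": [%s], "state": %s}',
                              badge, contacts, state_txt)]
  per_t <- per_badge[, .(body = paste(frag, collapse = ", ")), by = t]
  setorder(per_t, t)
  keys <- format_badge_datetime(.POSIXct(per_t$t, tz = .TZ))
  lines <- sprintf('"%s": {%s}', keys, per_t$body)
  txt <- paste0("{\n", paste(lines, collapse = ",\n"), "\n}")
  write_text_maybe_xz(txt, path, compressed)
}

#' Read an imputed history from JSON
#'
#' Accepts both sparse and dense files (seconds with no entries may or may
#' not be materialised). An anchor label appearing as a primary key is a
#' format violation and raises an error.
#'
#' @param path input path (`.xz` accepted), or JSON via `text =`.
#' @param shift optional [shift_spec()] fixing the history span; without
#'   it the span is the observed `[min, max + 1)` second range.
#' @param compressed logical; `NULL` auto-detects.
#' @param text JSON text instead of a file.
#' @return a `badge_history`; the `state` field is filled if any entry
#'   carries a non-null state.
#' @export
read_history <- function(path = NULL, shift = NULL, compressed = NULL, text = NULL) {
  txt <- if (is.null(text)) read_text_maybe_xz(path, compressed) else text
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (length(obj) == 0) {
    t0 <- if (!is.null(shift)) shift$start else .POSIXct(0, tz = .TZ)
    t1 <- if (!is.null(shift)) shift$end else .POSIXct(0, tz = .TZ)
    return(new_history(empty_contact_runs(), NULL, t0, t1, shift))
  }
  times <- as.numeric(parse_badge_datetime(names(obj)))
  o <- order(times)
  times <- times[o]; obj <- obj[o]
  n <- length(obj)
  c_chunks <- vector("list", n)
  s_chunks <- vector("list", n)
  any_state_field <- FALSE
  for (i in seq_len(n)) {
    ent <- obj[[i]]
    keys <- names(ent)
    bad <- keys[is_anchor(keys)]
    if (length(bad)) {
      stop("format violation: anchor label(s) as primary history key: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cs <- lapply(ent, function(z) as.character(unlist(z$contacts, use.names = FALSE)))
    len <- lengths(cs)
    if (any(len > 0)) {
      c_chunks[[i]] <- data.frame(badge = rep(keys, len),
                                  contact = unlist(cs, use.names = FALSE),
                                  t = times[i], stringsAsFactors = FALSE)
    }
    has_state <- !vapply(ent, function(z) is.null(z$state), logical(1))
    if (any(has_state)) {
      any_state_field <- TRUE
      rooms <- vapply(ent, function(z) {
        if (!is.null(z$state$room) && isTRUE(z$state$inroom))
          as.integer(z$state$room) else NA_integer_
      }, integer(1))
      if (any(!is.na(rooms))) {
        s_chunks[[i]] <- data.frame(badge = keys[!is.na(rooms)],
                                    room = rooms[!is.na(rooms)],
                                    t = times[i], stringsAsFactors = FALSE)
      }
    }
  }
  cc <- rbindlist(c_chunks[!vapply(c_chunks, is.null, logical(1))])
  ss <- rbindlist(s_chunks[!vapply(s_chunks, is.null, logical(1))])
  contacts <- if (nrow(cc)) seconds_to_runs(cc$badge, cc$contact, cc$t) else empty_contact_runs()
  state <- if (any_state_field) {
    if (nrow(ss)) state_seconds_to_runs(ss$badge, ss$t, ss$room) else empty_state_runs()
  } else NULL
  t0 <- if (!is.null(shift)) shift$start else .POSIXct(min(times), tz = .TZ)
  t1 <- if (!is.null(shift)) shift$end else .POSIXct(max(times) + 1, tz = .TZ)
  new_history(contacts, state, t0, t1, shift)
}

# collapse per-second (badge, contact, t) triples into half-open runs
seconds_to_runs <- function(badge, contact, t) {
  if (length(badge) == 0) return(empty_contact_runs())
  dt <- unique(data.table(badge = badge, contact = contact, t = t))
  setorder(dt, badge, contact, t)
  dt[, gid := cumsum(c(TRUE, diff(t) != 1)), by = .(badge, contact)]
  runs <- dt[, .(start = min(t), end = max(t) + 1), by = .(badge, contact, gid)]
  out <- data.frame(badge = runs$badge, contact = runs$contact,
                    start = .POSIXct(runs$start, tz = .TZ),
                    end = .POSIXct(runs$end, tz = .TZ),
                    stringsAsFactors = FALSE)
  out <- out[order(out$badge, out$start, out$contact), , drop = FALSE]
  rownames(out) <- NULL
  out
}

state_seconds_to_runs <- function(badge, t, room) {
  if (length(badge) == 0) return(empty_state_runs())
  dt <- unique(data.table(badge = badge, t = t, room = room))
  setorder(dt, badge, t)
  dt[, gid := cumsum(c(TRUE, diff(t) != 1 | diff(room) != 0)), by = badge]
  runs <- dt[, .(start = min(t), end = max(t) + 1, room = room[1]), by = .(badge, gid)]
  out <- data.frame(badge = runs$badge,
                    start = .POSIXct(runs$start, tz = .TZ),
                    end = .POSIXct(runs$end, tz = .TZ),
                    room = as.integer(runs$room), inroom = TRUE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$badge, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
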
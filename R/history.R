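# Imputed per-second contact histories.
#
# A history H spans one shift and maps each second t to a map from HCP
# badge to (i) the list of badges currently in contact and (ii) an
# inferred in-room state. Anchors never appear as primary keys -- only
# HCPs are tracked -- but anchors do appear inside contact lists, so
# location information survives through the symmetry of contacts.
#
# Internally the history is sparse: contacts are stored as half-open
# per-pair runs [start, end) and the per-second view is materialised on
# demand, which keeps a 12-hour shift cheap to hold in memory.

new_history <- function(contacts, state = NULL, t0, t1, shift = NULL) {
  structure(list(
    shift = shift,
    t0 = as_badge_time(t0), t1 = as_badge_time(t1),
    # contacts: data.frame(badge, contact, start, end) -- badge is an HCP,
    # runs are half-open [start, end) in seconds (POSIXct)
    contacts = contacts,
    # state: NULL until annotate_inroom(); then data.frame(badge, start,
    # end, room, inroom) holding the inroom-true episodes
    state = state
  ), class = "badge_history")
}

empty_contact_runs <- function() {
  data.frame(badge = character(), contact = character(),
             start = .POSIXct(numeric(), tz = .TZ),
             end = .POSIXct(numeric(), tz = .TZ),
             stringsAsFactors = FALSE)
}

empty_state_runs <- function() {
  data.frame(badge = character(),
             start = .POSIXct(numeric(), tz = .TZ),
             end = .POSIXct(numeric(), tz = .TZ),
             room = integer(), inroom = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.badge_history <- function(x, ...) {
  cat(sprintf("<badge_history: %s -- %s, %d HCP badge(s), %d contact run(s)%s%s>\n",
              format(x$t0, "%Y-%m-%d %H:%M:%S"), format(x$t1, "%Y-%m-%d %H:%M:%S"),
              length(unique(x$contacts$badge)), nrow(x$contacts),
              if (is.null(x$state)) ", unannotated" else ", in-room annotated",
              if (is.null(x$shift)) "" else sprintf(", shift %d", x$shift$index)))
  invisible(x)
}

is_annotated <- function(history) !is.null(history$state)

#' Impute a per-second contact history from contact intervals
#'
#' For each second `t` of the shift, every HCP badge participating in a
#' contact interval containing `t` (half-open `[start, start + duration)`)
#' gets an entry listing its partners. Symmetry between HCP badges is
#' forced: the (a,b) and (b,a) views are pooled per pair before imputing.
#' Anchors are omitted as primary entries but remain inside contact
#' lists; an interval between two anchors (which placement is designed to
#' prevent) is logged and excluded.
#'
#' @param intervals a `contact_intervals` data frame.
#' @param shift a [shift_spec()]; intervals are clipped to its span.
#' @param quiet suppress log lines.
#' @return a `badge_history` object.
#' @export
impute_history <- function(intervals, shift, quiet = FALSE) {
  stopifnot(is_shift_spec(shift))
  t0 <- as.numeric(shift$start); t1 <- as.numeric(shift$end)
  if (nrow(intervals) == 0) {
    return(new_history(empty_contact_runs(), NULL, t0, t1, shift))
  }
  s <- as.numeric(intervals$start_time)
  e <- s + intervals$duration_s
  anc_r <- is_anchor(intervals$reporter)
  anc_d <- is_anchor(intervals$detected)
  both_anchor <- anc_r & anc_d
  if (any(both_anchor)) {
    mt_log("excluded ", sum(both_anchor), " anchor-to-anchor interval(s)", quiet = quiet)
  }
  keep <- !both_anchor & e > t0 & s < t1
  if (!any(keep)) return(new_history(empty_contact_runs(), NULL, t0, t1, shift))
  s <- pmax(s[keep], t0); e <- pmin(e[keep], t1)
  a <- pmin(intervals$reporter[keep], intervals$detected[keep])
  b <- pmax(intervals$reporter[keep], intervals$detected[keep])
  dt <- data.table(a = a, b = b, s = s, e = e)
  setorder(dt, a, b, s, e)
  # pooling both directions and coalescing enforces symmetry per second
  dt[, gid := cumsum(s >= shift(cummax(e), fill = -Inf)), by = .(a, b)]
  runs <- dt[, .(s = min(s), e = max(e)), by = .(a, b, gid)]
  out <- rbind(
    data.frame(badge = runs$a, contact = runs$b, start = runs$s, end = runs$e),
    data.frame(badge = runs$b, contact = runs$a, start = runs$s, end = runs$e))
  out <- out[!is_anchor(out$badge), , drop = FALSE]   # anchors never primary
  out <- out[order(out$badge, out$start, out$contact), , drop = FALSE]
  out$start <- .POSIXct(out$start, tz = .TZ)
  out$end <- .POSIXct(out$end, tz = .TZ)
  rownames(out) <- NULL
  new_history(out, NULL, t0, t1, shift)
}

#' Per-second view of a history
#'
#' Materialises the entry map for one second: a named list from HCP badge
#' to `list(contacts = <character>, state = NULL | list(room, inroom))`.
#' Contacts are ordered by first-contact time (start of the current
#' contact run) and then label, so serialisation is deterministic.
#'
#' @param history a `badge_history`.
#' @param t a time (`POSIXct`, `datetime(...)` string, or seconds).
#' @return named list of entries (possibly empty).
#' @export
history_at <- function(history, t) {
  t <- as.numeric(as_badge_time(t))
  cr <- history$contacts
  hit <- cr[as.numeric(cr$start) <= t & t < as.numeric(cr$end), , drop = FALSE]
  badges <- sort(unique(hit$badge))
  entries <- lapply(badges, function(bg) {
    rows <- hit[hit$badge == bg, , drop = FALSE]
    rows <- rows[order(as.numeric(rows$start), rows$contact), , drop = FALSE]
    list(contacts = rows$contact, state = state_at(history, bg, t))
  })
  names(entries) <- badges
  entries
}

state_at <- function(history, badge, t) {
  if (!is_annotated(history)) return(NULL)
  st <- history$state
  row <- st[st$badge == badge & as.numeric(st$start) <= t & t < as.numeric(st$end), ,
            drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  list(room = as.integer(row$room[1]), inroom = isTRUE(row$inroom[1]))
}

#' Annotate a history with the door-vs-in-room inference
#'
#' A deterministic state machine scans each HCP badge's anchor contacts in
#' time order. Contact with an *interior* anchor of patient room `r`
#' (sink, computer workstation, or vitals monitor) sets the state to
#' `{room = r, inroom = TRUE}`: contact with the door anchor alone is
#' insufficient evidence of being in the room (an HCP may linger at, or
#' pass through, the doorway). A later contact with any anchor *outside*
#' room `r` -- another room's anchor (its door included) or a common-area
#' anchor -- clears the state; contact with room `r`'s own door anchor
#' leaves it unchanged. State is null at shift start. If interior anchors
#' of two rooms are in contact in the same second, the room whose anchor
#' contact began most recently wins; ties go to the smaller room number
#' and are logged.
#'
#' @param history a `badge_history` from [impute_history()].
#' @param placements an `anchor_placement` table covering every anchor
#'   seen in the history; a contact with an unknown anchor is an error.
#' @param quiet suppress log lines.
#' @return the history with its `state` field filled in.
#' @export
annotate_inroom <- function(history, placements, quiet = FALSE) {
  cr <- history$contacts
  anc <- cr[is_anchor(cr$contact), , drop = FALSE]
  missing <- setdiff(unique(anc$contact), placements$anchor)
  if (length(missing)) {
    stop("anchor(s) not in placements: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pl <- placements[match(anc$contact, placements$anchor), , drop = FALSE]
  anc$room <- pl$room
  anc$station <- pl$station
  anc$interior <- pl$station %in% .INTERIOR_STATIONS & is_patient_room(pl$room)
  t_end <- as.numeric(history$t1)
  states <- lapply(split(anc, anc$badge), annotate_one_badge,
                   t_end = t_end, quiet = quiet)
  st <- do.call(rbind, states)
  if (is.null(st) || nrow(st) == 0) st <- empty_state_runs()
  rownames(st) <- NULL
  history$state <- st
  history
}

# state machine over one badge's anchor-contact runs; runs are half-open
annotate_one_badge <- function(runs, t_end, quiet = FALSE) {
  s <- as.numeric(runs$start); e <- as.numeric(runs$end)
  bounds <- sort(unique(c(s, e)))
  cur_room <- NA_integer_
  out_badge <- runs$badge[1]
  res_start <- numeric(); res_end <- numeric(); res_room <- integer()
  seg_open <- NA_real_
  close_seg <- function(at) {
    if (!is.na(cur_room) && !is.na(seg_open) && at > seg_open) {
      res_start <<- c(res_start, seg_open)
      res_end <<- c(res_end, at)
      res_room <<- c(res_room, cur_room)
    }
  }
  for (bi in bounds) {
    if (bi >= t_end) break
    act <- which(s <= bi & bi < e)
    if (length(act) == 0) next   # state persists untouched
    rooms <- runs$room[act]
    interior <- runs$interior[act]
    new_room <- cur_room
    if (!is.na(cur_room) && any(rooms != as.character(cur_room))) {
      new_room <- NA_integer_    # contact with an anchor outside the room
    }
    if (any(interior)) {
      cand <- act[interior]
      # the most recently begun interior contact wins; ties -> smaller room
      latest <- max(s[cand])
      tied <- cand[s[cand] == latest]
      pick <- tied[order(as.integer(runs$room[tied]))][1]
      if (length(tied) > 1 && length(unique(runs$room[tied])) > 1) {
        mt_log("simultaneous interior-anchor contacts for ", out_badge,
               " at ", format_badge_datetime(.POSIXct(bi, tz = .TZ)),
               "; choosing room ", runs$room[pick], quiet = quiet)
      }
      new_room <- as.integer(runs$room[pick])
    }
    if (!identical(new_room, cur_room)) {
      close_seg(bi)
      cur_room <- new_room
      seg_open <- if (is.na(cur_room)) NA_real_ else bi
    }
  }
  close_seg(t_end)
  if (length(res_start) == 0) return(NULL)
  data.frame(badge = out_badge,
             start = .POSIXct(res_start, tz = .TZ),
             end = .POSIXct(res_end, tz = .TZ),
             room = res_room, inroom = TRUE,
             stringsAsFactors = FALSE)
}

#' Weighted contact graph over a time window
#'
#' Builds the undirected contact graph for the window `[t0, t1)`: an edge
#' joins two badges with weight equal to their number of seconds of
#' contact inside the window. For a whole-shift window every node stands
#' for one healthcare professional (badges are redistributed between
#' shifts), plus the anchors they touched.
#'
#' @param history a `badge_history`.
#' @param t0,t1 window bounds (`POSIXct`, strings, or seconds); must lie
#'   within the history span.
#' @param as `"edgelist"` (default) for a data frame of
#'   `from`/`to`/`weight` rows plus a `roles` attribute, or `"igraph"`
#'   for an igraph graph with a `role` vertex attribute (requires the
#'   igraph package).
#' @return see `as`.
#' @export
contact_graph <- function(history, t0 = history$t0, t1 = history$t1,
                          as = c("edgelist", "igraph")) {
  as <- match.arg(as)
  t0 <- as.numeric(as_badge_time(t0)); t1 <- as.numeric(as_badge_time(t1))
  if (t0 < as.numeric(history$t0) || t1 > as.numeric(history$t1)) {
    stop("window [t0, t1) must lie within the history span", call. = FALSE)
  }
  cr <- history$contacts
  u <- pmin(cr$badge, cr$contact); v <- pmax(cr$badge, cr$contact)
  dt <- unique(data.table(u = u, v = v,
                          s = as.numeric(cr$start), e = as.numeric(cr$end)))
  dt[, w := pmax(0, pmin(e, t1) - pmax(s, t0))]
  edges <- dt[, .(weight = sum(w)), by = .(u, v)][weight > 0]
  el <- data.frame(from = edges$u, to = edges$v, weight = as.numeric(edges$weight),
                   stringsAsFactors = FALSE)
  el <- el[order(el$from, el$to), , drop = FALSE]
  rownames(el) <- NULL
  nodes <- sort(unique(c(el$from, el$to)))
  roles <- data.frame(badge = nodes,
                      role = if (length(nodes)) role_of(nodes) else character(),
                      stringsAsFactors = FALSE)
  if (as == "edgelist") {
    attr(el, "roles") <- roles
    return(el)
  }
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as = \"igraph\"", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = roles)
  g
}
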
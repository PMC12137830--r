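# Anchor placement files.
#
# Four anchors sit in every patient room -- at the door, near the sink, at
# the computer workstation, and on the vitals monitor (the vitals monitor
# being a proxy for proximity to the patient's bed). Placement is recorded
# in layout-image pixel coordinates; anchors are installed so that no two
# anchors anywhere in the unit are within six feet of each other, which
# prevents anchor-to-anchor contacts.
#
# File dialect (YAML, versioned): a flat mapping from anchor label to
# room/station/x/y, plus a scenario-level pixels_per_foot scale used for
# the six-feet separation check:
#
#   format: micutrace-placement/1
#   pixels_per_foot: 10
#   anchors:
#     b001: {room: 1, station: door, x: 80, y: 155}

.STATIONS <- c("door", "sink", "computer", "vitals", "common")
.INTERIOR_STATIONS <- c("sink", "computer", "vitals")
.SIX_FEET_IN <- 72

#' Build an anchor placement table
#'
#' @param anchor anchor badge labels (`b`-prefixed).
#' @param room integer patient-room numbers, or character common-area
#'   labels for `station = "common"` anchors.
#' @param station one of `"door"`, `"sink"`, `"computer"`, `"vitals"`,
#'   `"common"` per anchor.
#' @param x,y layout-image pixel coordinates (origin top-left).
#' @param pixels_per_foot scale of the layout image, used for the six-feet
#'   anchor-separation check.
#' @param check validate invariants (default `TRUE`).
#' @return data frame of class `anchor_placement` with attribute
#'   `pixels_per_foot`.
#' @export
anchor_placement <- function(anchor, room, station, x, y,
                             pixels_per_foot = 10, check = TRUE) {
  df <- data.frame(anchor = as.character(anchor),
                   room = as.character(room),
                   station = as.character(station),
                   x = as.numeric(x), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  attr(df, "pixels_per_foot") <- as.numeric(pixels_per_foot)
  class(df) <- c("anchor_placement", "data.frame")
  if (check) validate_placement(df)
  df
}

is_patient_room <- function(room) grepl("^[0-9]+$", as.character(room))

#' Validate anchor-placement invariants
#'
#' Checks that all anchors have the anchor role, labels are unique, every
#' patient room has exactly one anchor of each of the four station types,
#' and no two anchors lie within six feet of each other at the stated
#' pixels-per-foot scale. Violations raise an error naming the offenders.
#'
#' @param placement an `anchor_placement` data frame.
#' @return the placement, invisibly.
#' @export
validate_placement <- function(placement) {
  df <- placement
  if (nrow(df) == 0) return(invisible(df))
  if (any(role_of(df$anchor) != "anchor")) {
    stop("non-anchor badge label(s) in placement: ",
         paste(df$anchor[role_of(df$anchor) != "anchor"], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$anchor)) {
    stop("duplicate anchor label(s): ",
         paste(unique(df$anchor[duplicated(df$anchor)]), collapse = ", "),
         call. = FALSE)
  }
  bad_station <- !df$station %in% .STATIONS
  if (any(bad_station)) {
    stop("unknown station type(s): ",
         paste(unique(df$station[bad_station]), collapse = ", "), call. = FALSE)
  }
  # every patient room has exactly one door/sink/computer/vitals anchor
  pr <- df[is_patient_room(df$room), , drop = FALSE]
  if (nrow(pr) > 0) {
    tab <- table(pr$room, factor(pr$station, levels = setdiff(.STATIONS, "common")))
    bad <- rownames(tab)[apply(tab, 1, function(z) any(z != 1L))]
    if (length(bad)) {
      stop("room(s) without exactly one anchor per station type: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  ppf <- attr(df, "pixels_per_foot") %||% 10
  d <- as.matrix(stats::dist(cbind(df$x, df$y))) / ppf * 12  # inches
  diag(d) <- Inf
  viol <- which(d <= .SIX_FEET_IN, arr.ind = TRUE)
  viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
  if (nrow(viol) > 0) {
    pairs <- apply(viol, 1, function(ij)
      sprintf("%s-%s (%.0f in)", df$anchor[ij[1]], df$anchor[ij[2]], d[ij[1], ij[2]]))
    stop("anchors within six feet of each other: ",
         paste(utils::head(pairs, 5L), collapse = "; "), call. = FALSE)
  }
  invisible(df)
}

#' Load / write an anchor placement file
#'
#' The placement file is a flat YAML mapping from anchor label to
#' `room`, `station`, `x`, `y`, with a top-level `pixels_per_foot` scale;
#' see the package vignette for the dialect. Loading validates all
#' placement invariants.
#'
#' @param path file path.
#' @return `load_placement()`: an `anchor_placement` data frame.
#' @export
load_placement <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$anchors)) stop("placement file has no 'anchors' mapping", call. = FALSE)
  labs <- names(doc$anchors)
  need <- c("room", "station", "x", "y")
  for (a in labs) {
    miss <- setdiff(need, names(doc$anchors[[a]]))
    if (length(miss)) {
      stop("anchor ", a, " missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  get1 <- function(f) vapply(doc$anchors, function(z) as.character(z[[f]]), character(1))
  anchor_placement(labs, get1("room"), get1("station"),
                   as.numeric(get1("x")), as.numeric(get1("y")),
                   pixels_per_foot = doc$pixels_per_foot %||% 10)
}

#' @rdname load_placement
#' @param placement an `anchor_placement` data frame.
#' @return `write_placement()`: the path, invisibly.
#' @export
write_placement <- function(placement, path) {
  anchors <- lapply(seq_len(nrow(placement)), function(i) {
    room <- placement$room[i]
    list(room = if (is_patient_room(room)) as.integer(room) else room,
         station = placement$station[i],
         x = placement$x[i], y = placement$y[i])
  })
  names(anchors) <- placement$anchor
  doc <- list(format = "micutrace-placement/1",
              pixels_per_foot = attr(placement, "pixels_per_foot") %||% 10,
              anchors = anchors)
  yaml::write_yaml(doc, path)
  invisible(path)
}
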
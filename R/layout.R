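# Synthetic MICU layout.
#
# Rooms are arranged in two rows along a central corridor. Each patient
# room is 16 x 16 ft and holds four anchor stations: the door on the
# corridor wall, the sink and the computer workstation on the back wall,
# and the vitals monitor next to the bed in mid-room. Station positions
# are chosen so that no two anchors anywhere in the unit are within six
# feet of each other (the installation rule that prevents anchor-to-anchor
# contacts). Optional common-area anchors sit on the corridor walk line at
# room boundaries, representing nurse-station beacons; the deployment
# emulated by the defaults had anchors in patient rooms only.
#
# Internal geometry is in feet (origin top-left, y increasing downward);
# the placement table is exported in layout-image pixels via the
# scenario's pixels-per-foot scale.

.ROOM_W <- 16; .ROOM_D <- 16; .CORRIDOR_D <- 14

#' Generate the simulated unit layout and anchor placement
#'
#' Deterministic for a given scenario: rooms are placed in two rows along
#' a central corridor, four anchors per room (door, sink, computer,
#' vitals) with pairwise separation above six feet, plus
#' `scenario$common_anchors` corridor anchors. Anchor labels are
#' `b001 ...` in room order (door, sink, computer, vitals within a room).
#'
#' @param scenario a [sim_scenario()].
#' @return an object of class `micu_layout`: a list with `placement` (an
#'   [anchor_placement()] table in pixels), `stations` (a data frame of
#'   dwell points in feet), `walk_y`, `entry`, and `extent` (feet).
#' @export
generate_layout <- function(scenario) {
  rooms <- scenario$rooms
  if (rooms < 1) stop("need at least one room", call. = FALSE)
  n_top <- ceiling(rooms / 2)
  corridor_y0 <- .ROOM_D
  walk_y <- corridor_y0 + .CORRIDOR_D / 2
  bot_y0 <- corridor_y0 + .CORRIDOR_D
  room_row <- function(r) if (r <= n_top) "top" else "bottom"
  room_x0 <- function(r) (if (r <= n_top) (r - 1) else (r - n_top - 1)) * .ROOM_W

  st <- list()
  for (r in seq_len(rooms)) {
    x0 <- room_x0(r)
    if (room_row(r) == "top") {
      pts <- rbind(door = c(x0 + 8, .ROOM_D - 0.5),
                   sink = c(x0 + 3.5, 3),
                   computer = c(x0 + 12.5, 3),
                   vitals = c(x0 + 8, 8))
    } else {
      pts <- rbind(door = c(x0 + 8, bot_y0 + 0.5),
                   sink = c(x0 + 3.5, bot_y0 + 13),
                   computer = c(x0 + 12.5, bot_y0 + 13),
                   vitals = c(x0 + 8, bot_y0 + 8))
    }
    st[[r]] <- data.frame(room = as.character(r), station = rownames(pts),
                          x = pts[, 1], y = pts[, 2], row = room_row(r),
                          stringsAsFactors = FALSE)
  }
  stations <- do.call(rbind, st)
  rownames(stations) <- NULL

  width <- n_top * .ROOM_W
  n_common <- scenario$common_anchors %||% 0L
  # nurse-station desks sit on the corridor walk line; when common-area
  # anchors are requested they are mounted at the desks. Desks go at room
  # boundaries (x multiples of the room width), which keeps any mounted
  # anchor well away from the door anchors at room centres.
  ns_x <- if (n_common > 0) {
    bnd <- seq(0, width, by = .ROOM_W)
    bnd[round(seq(1, length(bnd), length.out = n_common + 2))][seq_len(n_common) + 1L]
  } else {
    width * c(1, 2) / 3
  }
  if (n_common > 0) {
    # mounted a step off the walk line so passers-by are never inches away
    common <- data.frame(room = paste0("station", seq_len(n_common)),
                         station = "common", x = ns_x, y = walk_y + 4,
                         row = "corridor", stringsAsFactors = FALSE)
    stations <- rbind(stations, common)
  }

  ppf <- scenario$pixels_per_foot %||% 10
  placement <- anchor_placement(
    anchor = badge_label("anchor", seq_len(nrow(stations))),
    room = stations$room, station = stations$station,
    x = stations$x * ppf, y = stations$y * ppf,
    pixels_per_foot = ppf)

  structure(list(
    placement = placement,
    stations = stations,
    nurse_stations = data.frame(x = ns_x, y = walk_y),
    walk_y = walk_y,
    entry = c(x = -8, y = walk_y),
    extent = c(width = width, depth = bot_y0 + .ROOM_D),
    n_top = n_top,
    pixels_per_foot = ppf
  ), class = "micu_layout")
}

#' @export
print.micu_layout <- function(x, ...) {
  cat(sprintf("<micu_layout: %d room(s), %d anchor(s), %.0f x %.0f ft>\n",
              length(unique(x$stations$room[is_patient_room(x$stations$room)])),
              nrow(x$placement), x$extent["width"], x$extent["depth"]))
  invisible(x)
}
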
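# Shift-level descriptive statistics.
#
# mean_badge_count_per_bin() reproduces the high-level validation
# statistic: for each ten-minute interval of a day, the mean number of
# HCP badges having at least one contact (with another HCP badge or an
# anchor) during that interval, averaged separately over day and night
# shifts. A day of 600-second bins tiles into exactly 144 bins.

#' Mean HCP badge count per time-of-day bin
#'
#' For each time-of-day bin, counts the distinct HCP badges with at least
#' one second of contact (HCP or anchor) intersecting the bin on the
#' history's calendar day, then averages the counts separately over
#' day-shift and night-shift histories. Bins outside a history's span
#' contribute a count of zero for that history.
#'
#' @param histories a list of `badge_history` objects (one per shift).
#' @param bin_s bin width in seconds; must divide 86400 (default 600, i.e.
#'   ten minutes and 144 bins).
#' @return data frame with columns `bin` (0-based index), `tod`
#'   (`"HH:MM"` start of bin), `day_mean`, `night_mean` (NA when no
#'   history of that kind is supplied).
#' @export
mean_badge_count_per_bin <- function(histories, bin_s = 600L) {
  bin_s <- as.integer(bin_s)
  if (bin_s <= 0L || 86400L %% bin_s != 0L) {
    stop("bin_s must be a positive divisor of 86400", call. = FALSE)
  }
  if (inherits(histories, "badge_history")) histories <- list(histories)
  nbin <- 86400L %/% bin_s
  kinds <- vapply(histories, shift_kind_of, character(1))
  counts <- lapply(histories, badge_count_one, bin_s = bin_s, nbin = nbin)
  avg <- function(kind) {
    sel <- counts[kinds == kind]
    if (length(sel) == 0) return(rep(NA_real_, nbin))
    rowMeans(do.call(cbind, sel))
  }
  tod_s <- (seq_len(nbin) - 1L) * bin_s
  data.frame(bin = seq_len(nbin) - 1L,
             tod = sprintf("%02d:%02d", tod_s %/% 3600L, (tod_s %% 3600L) %/% 60L),
             day_mean = avg("day"),
             night_mean = avg("night"))
}

shift_kind_of <- function(history) {
  if (!is.null(history$shift)) return(history$shift$kind)
  # fall back on the starting hour: day shifts begin at 07:00
  h <- as.POSIXlt(history$t0, tz = .TZ)$hour
  if (h >= 7 && h < 19) "day" else "night"
}

# distinct badges with >= 1 contact second per time-of-day bin, one history
badge_count_one <- function(history, bin_s, nbin) {
  out <- numeric(nbin)
  cr <- history$contacts
  if (nrow(cr) == 0) return(out)
  s <- as.numeric(cr$start); e <- as.numeric(cr$end)
  # absolute bin range touched by each run (runs are half-open)
  b0 <- floor(s / bin_s); b1 <- floor((e - 1) / bin_s)
  reps <- as.integer(b1 - b0 + 1)
  badge <- rep(cr$badge, reps)
  absbin <- unlist(lapply(seq_along(b0), function(i) seq.int(b0[i], b1[i])),
                   use.names = FALSE)
  hit <- unique(data.frame(badge = badge, absbin = absbin))
  tod_bin <- as.integer(hit$absbin %% (86400 / bin_s))
  tab <- table(factor(tod_bin, levels = 0:(nbin - 1L)))
  out <- as.numeric(tab)
  out
}

#' Per-badge, per-room dwell time
#'
#' Total seconds each HCP badge spends with `inroom = TRUE` in each
#' patient room, from the in-room annotation. The sum over rooms never
#' exceeds the shift length for a badge.
#'
#' @param history an annotated `badge_history` (see [annotate_inroom()]).
#' @return data frame with columns `badge`, `room`, `seconds`.
#' @export
room_dwell_times <- function(history) {
  if (!is_annotated(history)) {
    stop("history has no in-room annotation; run annotate_inroom() first",
         call. = FALSE)
  }
  st <- history$state
  if (nrow(st) == 0) {
    return(data.frame(badge = character(), room = integer(), seconds = numeric()))
  }
  dur <- as.numeric(st$end) - as.numeric(st$start)
  agg <- stats::aggregate(dur, by = list(badge = st$badge, room = st$room), FUN = sum)
  out <- data.frame(badge = agg$badge, room = as.integer(agg$room),
                    seconds = as.numeric(agg$x))
  out <- out[order(out$badge, out$room), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transit times between patient rooms
#'
#' For each badge (optionally restricted to one role), every pair of
#' consecutive inroom-true episodes in two *different* rooms, with no
#' intervening inroom-true episode, yields one transit duration: the gap
#' between leaving the first room and entering the second. Consecutive
#' episodes in the same room yield nothing.
#'
#' @param history an annotated `badge_history`.
#' @param role optional role filter (`"nurse"`, `"provider"`,
#'   `"support"`).
#' @return data frame with columns `badge`, `from_room`, `to_room`,
#'   `depart`, `arrive`, `seconds`.
#' @export
transit_times <- function(history, role = NULL) {
  if (!is_annotated(history)) {
    stop("history has no in-room annotation; run annotate_inroom() first",
         call. = FALSE)
  }
  st <- history$state
  if (!is.null(role)) st <- st[role_of(st$badge) == role, , drop = FALSE]
  empty <- data.frame(badge = character(), from_room = integer(),
                      to_room = integer(),
                      depart = .POSIXct(numeric(), tz = .TZ),
                      arrive = .POSIXct(numeric(), tz = .TZ),
                      seconds = numeric())
  if (nrow(st) == 0) return(empty)
  st <- st[order(st$badge, st$start), , drop = FALSE]
  res <- lapply(split(st, st$badge), function(ep) {
    if (nrow(ep) < 2) return(NULL)
    i <- seq_len(nrow(ep) - 1L)
    diff_room <- ep$room[i] != ep$room[i + 1L]
    if (!any(diff_room)) return(NULL)
    i <- i[diff_room]
    data.frame(badge = ep$badge[i], from_room = ep$room[i],
               to_room = ep$room[i + 1L],
               depart = ep$end[i], arrive = ep$start[i + 1L],
               seconds = as.numeric(ep$start[i + 1L]) - as.numeric(ep$end[i]))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Plot mean badge counts by time of day
#'
#' Day and night series of [mean_badge_count_per_bin()] against time of
#' day. Requires ggplot2.
#'
#' @param counts output of [mean_badge_count_per_bin()].
#' @return a ggplot object.
#' @export
plot_badge_counts <- function(counts) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the ggplot2 package is required for plotting", call. = FALSE)
  }
  long <- rbind(
    data.frame(bin = counts$bin, mean = counts$day_mean, shift = "day"),
    data.frame(bin = counts$bin, mean = counts$night_mean, shift = "night"))
  ggplot2::ggplot(long, ggplot2::aes(x = bin * 10 / 60, y = mean, colour = shift)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hour of day", y = "mean HCP badges with a contact",
                  colour = "shift") +
    ggplot2::theme_minimal()
}
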
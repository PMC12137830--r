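# Shift structure: each day is divided into two 12-hour shifts.
# Day shifts run 07:00-19:00 and have even indices; night shifts run
# 19:00-07:00 with odd indices. Badge identities are only valid within a
# single shift (badges were redistributed each shift).

.SHIFT_HOURS <- 12L

#' Describe one 12-hour shift
#'
#' Shifts are indexed from 0; even indices are day shifts (07:00-19:00),
#' odd indices are night shifts (19:00-07:00). `first_day` is the calendar
#' date on which shift 0 begins at 07:00.
#'
#' @param index shift index (non-negative integer).
#' @param first_day `Date` (or string) of shift 0's morning.
#' @return object of class `shift_spec` with fields `index`, `kind`
#'   (`"day"` or `"night"`), `start`, `end` (`POSIXct`).
#' @export
#' @examples
#' shift_spec(2, first_day = "2023-04-20")
shift_spec <- function(index, first_day = "2023-04-20") {
  index <- as.integer(index)
  stopifnot(length(index) == 1L, index >= 0L)
  day0 <- as.Date(first_day)
  start <- as.POSIXct(paste(day0, "07:00:00"), tz = .TZ) + index * .SHIFT_HOURS * 3600
  structure(
    list(index = index,
         kind = if (index %% 2L == 0L) "day" else "night",
         start = start,
         end = start + .SHIFT_HOURS * 3600),
    class = "shift_spec")
}

#' @rdname shift_spec
#' @param indices integer vector of shift indices.
#' @return `shift_plan()`: a list of `shift_spec` objects.
#' @export
shift_plan <- function(indices = 1:14, first_day = "2023-04-20") {
  lapply(indices, shift_spec, first_day = first_day)
}

#' @export
print.shift_spec <- function(x, ...) {
  cat(sprintf("<shift %d (%s): %s -- %s>\n", x$index, x$kind,
              format(x$start, "%Y-%m-%d %H:%M"), format(x$end, "%Y-%m-%d %H:%M")))
  invisible(x)
}

is_shift_spec <- function(x) inherits(x, "shift_spec")
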
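# Internal helpers: the datetime-string dialect, seed scoping, logging.

# All pipeline times are naive local time stored as POSIXct in tz = "UTC".
.TZ <- "UTC"

#' Parse datetime strings of the form `datetime(Y,M,D,h,m,s)`
#'
#' The raw-record and history files encode timestamps as the string form of
#' a Python `datetime` constructor call, e.g. `"datetime(2023,4,25,7,39,43)"`.
#' Parsing is liberal: surrounding quotes and spaces after commas are
#' accepted. [format_badge_datetime()] always emits the canonical
#' no-space, unquoted form.
#'
#' @param x character vector of datetime strings.
#' @return `POSIXct` vector (naive local time, tz `"UTC"`).
#' @seealso [format_badge_datetime()]
#' @export
#' @examples
#' parse_badge_datetime("datetime(2023,4,25,7,39,43)")
parse_badge_datetime <- function(x) {
  x <- trimws(x)
  x <- sub('^"', "", x)
  x <- sub('"$', "", x)
  pat <- "^datetime\\(\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*\\)$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("unparseable datetime string(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  m <- regmatches(x, regexec(pat, x))
  f <- vapply(m, function(g) {
    g <- as.integer(g[-1])
    ISOdatetime(g[1], g[2], g[3], g[4], g[5], g[6], tz = .TZ)
  }, numeric(1))
  .POSIXct(f, tz = .TZ)
}

#' Format timestamps in the canonical `datetime(Y,M,D,h,m,s)` form
#'
#' @param t `POSIXct` vector.
#' @return character vector, no zero padding, no spaces.
#' @export
format_badge_datetime <- function(t) {
  lt <- as.POSIXlt(t, tz = .TZ)
  sprintf("datetime(%d,%d,%d,%d,%d,%d)",
          lt$year + 1900L, lt$mon + 1L, lt$mday,
          lt$hour, lt$min, as.integer(lt$sec))
}

as_badge_time <- function(x) {
  if (inherits(x, "POSIXct")) return(.POSIXct(as.numeric(x), tz = .TZ))
  if (is.character(x)) return(parse_badge_datetime(x))
  if (is.numeric(x)) return(.POSIXct(x, tz = .TZ))
  stop("cannot interpret value of class ", class(x)[1], " as a time")
}

# run code with a local RNG state; never disturbs the caller's stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a per-stream seed from a base seed; stays inside 32-bit range
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %% 2147483647
}

gcd2 <- function(a, b) {
  while (b != 0) { r <- a %% b; a <- b; b <- r }
  a
}

#' Greatest common divisor of a vector of non-negative integers
#' @param x integer vector.
#' @return a single integer; 0 for an empty vector.
#' @export
gcd_all <- function(x) {
  x <- abs(as.numeric(x))
  if (length(x) == 0) return(0)
  Reduce(gcd2, x)
}

mt_log <- function(..., quiet = FALSE) {
  if (!quiet) message("[micutrace] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
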
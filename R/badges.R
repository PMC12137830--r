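# Badge labels and roles.
#
# A badge label is a role prefix followed by a zero-padded integer:
# "b037" (anchor 37), "pr015" (provider), "n008" (nurse), "ss044"
# (support staff). The prefix alone determines the role.

.ROLE_PREFIX <- c(anchor = "b", provider = "pr", nurse = "n", support = "ss")

#' Role of a badge label
#'
#' Badge labels carry their role as a prefix: `b` for a stationary anchor,
#' `pr` for a provider (physician), `n` for a nurse, and `ss` for support
#' staff. `role_of()` is total on such labels and rejects everything else.
#'
#' @param badge character vector of badge labels.
#' @return character vector with values in
#'   `c("anchor", "provider", "nurse", "support")`.
#' @export
#' @examples
#' role_of(c("b097", "n008", "pr015", "ss044"))
role_of <- function(badge) {
  badge <- as.character(badge)
  role <- rep(NA_character_, length(badge))
  role[grepl("^ss[0-9]+$", badge)] <- "support"
  role[grepl("^pr[0-9]+$", badge)] <- "provider"
  role[grepl("^n[0-9]+$", badge)]  <- "nurse"
  role[grepl("^b[0-9]+$", badge)]  <- "anchor"
  if (anyNA(role)) {
    stop("invalid badge label(s): ",
         paste(unique(badge[is.na(role)]), collapse = ", "), call. = FALSE)
  }
  role
}

#' Test badge labels for validity / anchor role
#' @param badge character vector.
#' @return logical vector.
#' @export
is_valid_badge <- function(badge) {
  grepl("^(ss|pr|n|b)[0-9]+$", as.character(badge))
}

#' @rdname is_valid_badge
#' @export
is_anchor <- function(badge) {
  grepl("^b[0-9]+$", as.character(badge))
}

#' Construct badge labels from a role and index
#'
#' @param role one of `"anchor"`, `"provider"`, `"nurse"`, `"support"`
#'   (recycled).
#' @param index positive integers.
#' @param width zero-padding width (default 3, matching labels such as
#'   `b037` and `ss044`).
#' @return character vector of labels.
#' @export
#' @examples
#' badge_label("anchor", 37)
badge_label <- function(role, index, width = 3L) {
  role <- match.arg(role, names(.ROLE_PREFIX), several.ok = TRUE)
  paste0(.ROLE_PREFIX[role], formatC(as.integer(index), width = width, flag = "0"))
}
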
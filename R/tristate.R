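#' Tristate clinical flags
#'
#' Clinical findings in an HLM record are tristate: \code{"present"},
#' \code{"absent"} or \code{"unknown"}. The distinction between
#' \emph{unknown} (not assessed / not reported) and \emph{absent}
#' (assessed and negative) is preserved everywhere: the stage engines are
#' conservative and an unknown flag never satisfies a staging criterion.
#'
#' \code{as_tristate()} normalises common encodings: logical
#' \code{TRUE}/\code{FALSE}, numeric \code{1}/\code{0}, the strings
#' \code{"present"}/\code{"absent"}/\code{"unknown"} (case-insensitive),
#' \code{"yes"}/\code{"no"}, and \code{NA} or \code{""} (both mapped to
#' \code{"unknown"}).
#'
#' @param x a scalar value in any of the accepted encodings.
#' @return a character scalar, one of \code{"present"}, \code{"absent"},
#'   \code{"unknown"}.
#' @examples
#' as_tristate(1)
#' as_tristate(NA)
#' as_tristate("Absent")
#' @export
as_tristate <- function(x) {
  if (length(x) != 1L) stop("tristate values are scalars", call. = FALSE)
  if (is.na(x)) return("unknown")
  if (is.logical(x)) return(if (x) "present" else "absent")
  if (is.numeric(x)) {
    if (x == 1) return("present")
    if (x == 0) return("absent")
    stop("numeric tristate must be 0 or 1, got ", x, call. = FALSE)
  }
  s <- tolower(trimws(as.character(x)))
  if (s %in% c("present", "1", "true", "yes")) return("present")
  if (s %in% c("absent", "0", "false", "no")) return("absent")
  if (s %in% c("unknown", "", "na")) return("unknown")
  stop("cannot interpret '", x, "' as a tristate flag", call. = FALSE)
}

is_tristate <- function(x) {
  is.character(x) && length(x) == 1L && x %in% c("present", "absent", "unknown")
}

#' Kleene three-valued logic over tristate flags
#'
#' `tri_or()` is \code{"present"} if any argument is present, else
#' \code{"unknown"} if any is unknown, else \code{"absent"}. `tri_and()`
#' is dual. `tri_not()` swaps present/absent. These implement the strong
#' Kleene connectives, which is exactly the conservative semantics the
#' stage engines need: evidence must be positively present to fire a rule.
#'
#' @param ... tristate scalars.
#' @param x a tristate scalar.
#' @return a tristate scalar.
#' @export
tri_or <- function(...) {
  v <- c(...)
  if (any(v == "present")) "present"
  else if (any(v == "unknown")) "unknown"
  else "absent"
}

#' @rdname tri_or
#' @export
tri_and <- function(...) {
  v <- c(...)
  if (any(v == "absent")) "absent"
  else if (any(v == "unknown")) "unknown"
  else "present"
}

#' @rdname tri_or
#' @export
tri_not <- function(x) {
  switch(x, present = "absent", absent = "present", "unknown")
}

# Range flags extend tristates with the side of the excursion:
# "within", "below", "above", "unknown".
is_rangeflag <- function(x) {
  is.character(x) && length(x) == 1L &&
    x %in% c("within", "below", "above", "unknown")
}

#' Flag a measurement against a closed reference interval
#'
#' Boundary values count as within the interval (closed comparison).
#' A missing measurement flags \code{"unknown"}.
#'
#' @param x numeric scalar or NA.
#' @param interval numeric length-2 vector \code{c(lower, upper)}.
#' @return one of \code{"within"}, \code{"below"}, \code{"above"},
#'   \code{"unknown"}.
#' @export
range_flag <- function(x, interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  if (is.null(x) || length(x) == 0L || is.na(x)) return("unknown")
  if (x < interval[1]) "below"
  else if (x > interval[2]) "above"
  else "within"
}
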
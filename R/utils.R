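# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used everywhere a count of persons or an
#' amount of money is rounded: 0.5 always rounds up, unlike [base::round()]
#' which rounds half to even. Tables of whole persons and whole dollars in
#' national planning documents use this convention.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places to keep (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4999))
#' round_half_up(807.498)  # stays 807
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Classed conditions so callers can distinguish bad input (missing file,
# unparseable text) from semantic validation failures.
mh_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "mh_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(fmt, ...) mh_stop("mh_validation_error", fmt, ...)
stop_input <- function(fmt, ...) mh_stop("mh_input_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

check_scalar_prob <- function(x, name, lo = 0, hi = 1,
                              lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_validation("'%s' must be a single number in %s%g, %g%s (got %s)",
                    name, if (lo_open) "(" else "[", lo, hi,
                    if (hi_open) ")" else "]",
                    paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# Format a double so that read-back with as.numeric() is bit-exact
# (17 significant digits; integers without exponent notation).
fmt_full <- function(x) {
  out <- character(length(x))
  int <- !is.na(x) & is.finite(x) & x == floor(x) & abs(x) < 2^53
  out[int] <- formatC(x[int], format = "f", digits = 0)
  out[!int] <- formatC(x[!int], format = "g", digits = 17)
  out[is.na(x)] <- NA_character_
  out
}
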
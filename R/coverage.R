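# Coverage scale-up trajectories.
#
# A trajectory is the annual sequence of coverage percentages an intervention
# follows from its baseline (first horizon year) to its target (last horizon
# year). Four interpolation patterns are supported; published per-year rows
# can be supplied verbatim instead and always take precedence.

coverage_patterns <- function() c("linear", "front_loaded", "s_shaped", "exponential")

new_trajectory <- function(values, years, intervention, pattern) {
  stopifnot(length(values) == length(years))
  structure(
    as.numeric(values),
    names = as.character(years),
    intervention = intervention,
    pattern = pattern,
    class = "coverage_trajectory"
  )
}

validate_trajectory <- function(traj, what = "coverage trajectory") {
  v <- as.numeric(traj)
  if (length(v) < 1L) stop_validation("%s is empty", what)
  if (any(!is.finite(v))) stop_validation("%s contains non-finite values", what)
  if (any(v < 0 | v > 100)) {
    stop_validation("%s has values outside [0, 100]: %s", what,
                    paste(format(v[v < 0 | v > 100]), collapse = ", "))
  }
  if (length(v) > 1L && any(diff(v) < -1e-9)) {
    i <- which(diff(v) < -1e-9)[1L]
    stop_validation("%s decreases between steps %d and %d (%g -> %g)",
                    what, i, i + 1L, v[i], v[i + 1L])
  }
  invisible(traj)
}

#' Interpolate a coverage scale-up trajectory
#'
#' Connects a baseline coverage (first year) to a target coverage (last year)
#' over `n_steps` annual steps under one of four patterns:
#'
#' * `linear`: equal annual increments.
#' * `front_loaded`: coverage gains concentrated in the early years, with
#'   annual increments that never increase -- the shape recommended for
#'   middle-income settings where delivery infrastructure already exists.
#'   Implemented as a power curve \eqn{c(t) = b + (T-b)(t/N)^p} with
#'   exponent `power` (default 0.5).
#' * `s_shaped`: slow start, fast middle, slow finish (smoothstep polynomial
#'   \eqn{3x^2 - 2x^3}); increments rise then fall.
#' * `exponential`: gains concentrated late; increments never decrease.
#'   Implemented as a normalized exponential \eqn{(e^{kx}-1)/(e^k-1)} with
#'   rate `rate` (default 3).
#'
#' Endpoints are pinned exactly: the first value is `baseline_pct` and the
#' last is `target_pct` for every pattern. For identical endpoints all
#' patterns return the constant trajectory. At interior years the patterns
#' are ordered pointwise: front-loaded >= linear >= exponential.
#'
#' @param baseline_pct,target_pct Coverage percentages in \[0, 100\] with
#'   `baseline_pct <= target_pct`.
#' @param n_steps Number of annual steps (>= 1); the trajectory has
#'   `n_steps + 1` values.
#' @param pattern One of `"linear"`, `"front_loaded"`, `"s_shaped"`,
#'   `"exponential"`.
#' @param years Optional calendar-year labels (length `n_steps + 1`);
#'   defaults to step indices `0:n_steps`.
#' @param intervention Optional intervention id carried as an attribute.
#' @param power Exponent of the front-loaded power curve (0 < power < 1).
#' @param rate Rate constant of the exponential curve (> 0).
#' @return A `coverage_trajectory`: numeric vector of percentages named by
#'   year, with `intervention` and `pattern` attributes.
#' @examples
#' coverage_interpolate(1, 30, 10, "linear")       # 1, 3.9, 6.8, ..., 30
#' coverage_interpolate(40, 70, 10, "front_loaded")
#' @export
coverage_interpolate <- function(baseline_pct, target_pct, n_steps,
                                 pattern = c("linear", "front_loaded",
                                             "s_shaped", "exponential"),
                                 years = NULL, intervention = NA_character_,
                                 power = 0.5, rate = 3) {
  pattern <- match.arg(pattern)
  check_scalar_prob(baseline_pct, "baseline_pct", 0, 100)
  check_scalar_prob(target_pct, "target_pct", 0, 100)
  if (baseline_pct > target_pct) {
    stop_validation("baseline_pct (%g) exceeds target_pct (%g)",
                    baseline_pct, target_pct)
  }
  if (!is_count(n_steps) || n_steps < 1) {
    stop_validation("n_steps must be a positive integer (got %s)",
                    paste(format(n_steps), collapse = ","))
  }
  check_scalar_prob(power, "power", 0, 1, lo_open = TRUE, hi_open = TRUE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_validation("rate must be a positive number")
  }

  t <- 0:n_steps
  gap <- target_pct - baseline_pct
  values <- switch(pattern,
    # multiply before dividing so rows printed to one decimal come out exact
    linear = baseline_pct + gap * t / n_steps,
    front_loaded = baseline_pct + gap * (t / n_steps)^power,
    s_shaped = {
      x <- t / n_steps
      baseline_pct + gap * (3 * x^2 - 2 * x^3)
    },
    exponential = baseline_pct + gap * expm1(rate * t / n_steps) / expm1(rate)
  )
  values[1L] <- baseline_pct
  values[n_steps + 1L] <- target_pct
  if (is.null(years)) years <- t
  if (length(years) != n_steps + 1L) {
    stop_validation("years must have length n_steps + 1")
  }
  validate_trajectory(
    new_trajectory(values, years, intervention, pattern),
    what = sprintf("interpolated trajectory (%s)", pattern)
  )
}

#' Build a coverage trajectory from explicit per-year percentages
#'
#' Wraps a published (or otherwise externally fixed) row of annual coverage
#' percentages as a trajectory. Explicit rows override any interpolation
#' pattern: when a table row exists for an intervention it is authoritative.
#'
#' @param percents Numeric vector of coverage percentages, one per horizon
#'   year, non-decreasing and within \[0, 100\].
#' @param years Optional calendar-year labels (same length as `percents`).
#' @param intervention Optional intervention id.
#' @return A `coverage_trajectory`.
#' @examples
#' coverage_from_table(c(40, 43, 46, 49, 52, 55, 58, 61, 64, 67, 70),
#'                     years = 2020:2030)
#' @export
coverage_from_table <- function(percents, years = NULL,
                                intervention = NA_character_) {
  if (!is.numeric(percents) || length(percents) < 1L) {
    stop_validation("percents must be a non-empty numeric vector")
  }
  if (is.null(years)) years <- seq_along(percents) - 1L
  if (length(years) != length(percents)) {
    stop_validation("intervention '%s': %d coverage values supplied for %d years",
                    intervention, length(percents), length(years))
  }
  validate_trajectory(
    new_trajectory(percents, years, intervention, "from_table"),
    what = sprintf("coverage table row for '%s'", intervention)
  )
}

#' Annual coverage increments of a trajectory
#'
#' First differences of the trajectory, in percentage points. Increments are
#' non-negative and telescope: they sum to target minus baseline.
#'
#' @param trajectory A `coverage_trajectory`.
#' @return Numeric vector of length one less than the trajectory (empty for
#'   a single-year horizon), named by the year each increment lands in.
#' @examples
#' coverage_increments(coverage_interpolate(1, 30, 10, "linear"))
#' @export
coverage_increments <- function(trajectory) {
  validate_trajectory(trajectory)
  v <- as.numeric(trajectory)
  if (length(v) < 2L) {
    return(setNames(numeric(0), character(0)))
  }
  setNames(diff(v), names(trajectory)[-1L])
}

#' @export
print.coverage_trajectory <- function(x, ...) {
  cat(sprintf("Coverage trajectory [%s, pattern=%s]\n",
              attr(x, "intervention") %||% "?", attr(x, "pattern") %||% "?"))
  print(round(setNames(as.numeric(x), names(x)), 1))
  invisible(x)
}
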
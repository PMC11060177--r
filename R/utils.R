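#' Round half away from zero
#'
#' Display rounding used throughout the package: ties go up (1.15 -> 1.2),
#' unlike [base::round()]'s round-half-even. Used wherever a value is
#' reported at the precision of the study's printed tables.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Convert a flow rate from uL/min to cm3/day
#'
#' Flow logs are recorded in uL/min; all internal volumes are cm3 and time is
#' in days, so 1 uL/min = 1.44 cm3/day.
#'
#' @param x flow rate(s), uL/min
#' @return flow rate(s), cm3/day
#' @export
ulmin_to_cm3day <- function(x) x * 1440 * 1e-3

# internal argument checks -----------------------------------------------

assert_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and >= 0", name), call. = FALSE)
  }
  invisible(x)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Evaluate a piecewise-constant daily profile at time t (days).
# `profile` is either a single number (constant) or a data.frame with
# columns day (start day of the regime) and value; the value holds from its
# day until the next breakpoint.
profile_at <- function(profile, t) {
  if (is.numeric(profile) && length(profile) == 1L) return(rep(profile, length(t)))
  stopifnot(is.data.frame(profile), all(c("day", "value") %in% names(profile)))
  o <- order(profile$day)
  day <- profile$day[o]
  val <- profile$value[o]
  idx <- findInterval(t, day)
  out <- ifelse(idx == 0, val[1], val[pmax(idx, 1)])
  as.numeric(out)
}

# Normalise a user-supplied profile spec into the canonical data.frame form.
as_profile <- function(x, name) {
  if (is.numeric(x) && length(x) == 1L) {
    assert_nonneg(x, name)
    return(data.frame(day = 0, value = as.numeric(x)))
  }
  if (is.data.frame(x)) {
    cols <- names(x)
    if (ncol(x) == 2L && !all(c("day", "value") %in% cols)) {
      names(x) <- c("day", "value")
    }
    if (!all(c("day", "value") %in% names(x))) {
      stop(sprintf("'%s' must have columns day and value", name), call. = FALSE)
    }
    assert_nonneg(x$value, name)
    return(x[order(x$day), c("day", "value")])
  }
  stop(sprintf("'%s' must be a single number or a data.frame(day, value)", name),
       call. = FALSE)
}
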
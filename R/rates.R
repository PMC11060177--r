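#' Zero-order sulfate-reduction rate by linear regression
#'
#' Ordinary least-squares fit of mean outlet sulfate concentration (mM)
#' against time (days); the rate is the negative slope, so a depleting
#' reactor gives a positive rate. Because 1 mM = 1 umol/cm3, the slope in
#' mM/day is numerically the volumetric rate in umol/(day cm3) of void
#' porewater. A rising sulfate series yields a negative rate, not an
#' error. The fit is unweighted (replicate SDs are ignored); set
#' `weighted = TRUE` for inverse-variance weights.
#'
#' @param series a [porewater_series()]; only the sulfate rows are used
#' @param window optional `c(start, end)` day range (inclusive)
#' @param weighted inverse-variance weighting by replicate SD (default
#'   FALSE, matching the plain adjusted R-squared reporting convention)
#' @return a `rate_estimate` with fields rate, se (slope standard error),
#'   adj_r2, method = "linear_regression", window
#' @export
linear_rate <- function(series, window = NULL, weighted = FALSE) {
  stopifnot(inherits(series, "porewater_series"))
  x <- series[series$analyte == "sulfate", , drop = FALSE]
  if (!is.null(window)) {
    x <- x[x$day >= window[1] & x$day <= window[2], , drop = FALSE]
  }
  if (nrow(x) < 3) {
    stop("at least 3 sulfate sampling days are required", call. = FALSE)
  }
  if (stats::var(x$day) == 0) {
    stop("sampling days have zero variance", call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    s <- pmax(x$sd, 1e-8)
    w <- 1 / s^2
  }
  fit <- stats::lm(mean ~ day, data = x, weights = w)
  # exactly linear series are legitimate input (se 0, adj R2 1), so the
  # "essentially perfect fit" advisory is muffled
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  rate_estimate(
    rate = -unname(stats::coef(fit)["day"]),
    se = unname(sm$coefficients["day", "Std. Error"]),
    adj_r2 = sm$adj.r.squared,
    method = "linear_regression",
    window = range(x$day)
  )
}

#' Sulfate-reduction rate by global mass balance
#'
#' The budget estimator: all sulfate supplied (injected porewater at the
#' inflow concentration, plus the sulfate held in gypsum) minus all sulfate
#' accounted for at the end (weekly outflow export, plus the final
#' dissolved pool in the voids), normalised by duration and void volume:
#'
#' \deqn{rate = \frac{V_{in}^{tot} [SO_4]_{in} + n_{gypsum}
#'   - \sum_w V_w [SO_4]_{out,w} - V_{voids} [SO_4]_{out}^{end}}
#'   {days \cdot V_{voids}}}
#'
#' Volumes in L, concentrations in mM, void volume in cm3; the result is
#' umol/(day cm3 void). For a closed system, count the initial saturation
#' fill as injected water (`v_in_tot = v_voids/1000` at the initial
#' concentration). A negative numerator (net sulfate accumulation) is
#' permitted and flagged, not an error.
#'
#' @param inputs a [mass_balance_inputs()] list
#' @return a `rate_estimate` with method = "mass_balance"; the sulfate
#'   budget (numerator, mmol consumed) is attached as `$budget_mmol` and a
#'   logical `$accumulation` flag marks negative budgets
#' @export
mass_balance_rate <- function(inputs) {
  stopifnot(inherits(inputs, "mass_balance_inputs"))
  outflow <- sum(inputs$weekly_outflow$volume * inputs$weekly_outflow$c_out)
  numerator <- inputs$v_in_tot * inputs$c_in + inputs$n_gypsum -
    outflow - (inputs$v_voids / 1000) * inputs$c_out_end
  est <- rate_estimate(
    rate = numerator * 1000 / (inputs$days * inputs$v_voids),
    se = NA_real_, adj_r2 = NA_real_,
    method = "mass_balance",
    window = c(0, inputs$days)
  )
  est$budget_mmol <- numerator
  est$accumulation <- numerator < 0
  if (est$accumulation) {
    warning("negative sulfate budget: net accumulation over the run",
            call. = FALSE)
  }
  est
}

#' Assemble global mass-balance inputs
#'
#' Either supply every symbol directly, or derive them from a
#' [simulate_reactor()] run (`mass_balance_inputs_from_sim()`), which bins
#' the simulated outflow into weeks with flow-weighted mean concentrations
#' and uses the actually-dissolved gypsum.
#'
#' @param v_in_tot total water volume injected, L (for a closed system,
#'   the initial saturation fill `v_voids/1000`)
#' @param c_in inflow sulfate concentration, mM
#' @param n_gypsum sulfate supplied by gypsum dissolution, mmol
#' @param weekly_outflow data.frame with columns `volume` (L) and `c_out`
#'   (mean outflow sulfate that week, mM)
#' @param v_voids void volume, cm3
#' @param c_out_end final outflow sulfate concentration, mM
#' @param days experiment duration, days
#' @return an object of class `mass_balance_inputs`
#' @export
mass_balance_inputs <- function(v_in_tot, c_in, n_gypsum, weekly_outflow,
                                v_voids, c_out_end, days) {
  assert_nonneg(v_in_tot, "v_in_tot")
  assert_nonneg(c_in, "c_in")
  assert_nonneg(n_gypsum, "n_gypsum")
  assert_pos(v_voids, "v_voids")
  assert_pos(days, "days")
  assert_nonneg(c_out_end, "c_out_end")
  if (is.null(weekly_outflow) || nrow(weekly_outflow) == 0) {
    weekly_outflow <- data.frame(volume = numeric(0), c_out = numeric(0))
  }
  stopifnot(all(c("volume", "c_out") %in% names(weekly_outflow)))
  assert_nonneg(weekly_outflow$volume, "weekly_outflow$volume")
  if (sum(weekly_outflow$volume) > v_in_tot + v_voids / 1000 + 1e-9) {
    stop("weekly outflow volumes exceed water supplied plus void volume",
         call. = FALSE)
  }
  structure(list(v_in_tot = v_in_tot, c_in = c_in, n_gypsum = n_gypsum,
                 weekly_outflow = weekly_outflow, v_voids = v_voids,
                 c_out_end = c_out_end, days = days),
            class = "mass_balance_inputs")
}

#' @rdname mass_balance_inputs
#' @param sim a `reactor_sim`
#' @param bin_days width of the outflow bins, days (default 7)
#' @export
mass_balance_inputs_from_sim <- function(sim, bin_days = 7) {
  stopifnot(inherits(sim, "reactor_sim"))
  cfg <- sim$config
  traj <- sim$trajectory
  fill <- cfg$v_voids / 1000                       # initial saturation, L
  v_in_tot <- fill + sim$totals$vol_in
  # effective inflow concentration: initial fill at c0, later water at c_in
  c_in_eff <- (fill * cfg$c0_sulfate + sim$totals$vol_in * cfg$c_in_sulfate) /
    v_in_tot
  edges <- unique(c(seq(0, cfg$duration, by = bin_days), cfg$duration))
  vol <- stats::approx(traj$day, traj$vol_in, xout = edges)$y
  exp_so4 <- stats::approx(traj$day, traj$exp_so4, xout = edges)$y
  dv <- diff(vol)
  dm <- diff(exp_so4)
  keep <- dv > 0
  weekly <- data.frame(volume = dv[keep], c_out = dm[keep] / dv[keep])
  mass_balance_inputs(
    v_in_tot = v_in_tot, c_in = c_in_eff,
    n_gypsum = sim$totals$gyp_dissolved,
    weekly_outflow = weekly,
    v_voids = cfg$v_voids,
    c_out_end = sim$final$sulfate,
    days = cfg$duration
  )
}

#' Split a series at a breakpoint and estimate a rate on each side
#'
#' Applies [linear_rate()] to `[start, breakpoint]` and
#' `(breakpoint, end]` independently, e.g. to isolate a low-flow regime
#' from a later high-flow regime. A side with fewer than 3 sampling days
#' yields an `NA` estimate with a warning rather than an abort.
#'
#' @param series a [porewater_series()]
#' @param breakpoint day at which to split (must lie within the observed
#'   range)
#' @return list of two `rate_estimate`s (`before`, `after`)
#' @export
windowed_rate <- function(series, breakpoint) {
  stopifnot(inherits(series, "porewater_series"))
  d <- series$day[series$analyte == "sulfate"]
  if (breakpoint < min(d) || breakpoint > max(d)) {
    stop("'breakpoint' must lie within the observed day range", call. = FALSE)
  }
  fit_side <- function(lo, hi, open_lo) {
    x <- series[series$analyte == "sulfate", ]
    sel <- if (open_lo) x$day > lo & x$day <= hi else x$day >= lo & x$day <= hi
    if (sum(sel) < 3) {
      warning(sprintf("window (%g, %g] has fewer than 3 points; estimate is NA",
                      lo, hi), call. = FALSE)
      return(rate_estimate(NA_real_, NA_real_, NA_real_,
                           "linear_regression", c(lo, hi)))
    }
    linear_rate(series, window = c(if (open_lo) lo + 1e-9 else lo, hi))
  }
  list(before = fit_side(min(d), breakpoint, open_lo = FALSE),
       after = fit_side(breakpoint, max(d), open_lo = TRUE))
}

#' Summarise rates across reactors
#'
#' Arithmetic mean, sample SD (n-1 denominator) and relative standard
#' deviation of a set of same-method rate estimates, as used to report the
#' cross-reactor average rate and its RSD.
#'
#' @param rates a list of `rate_estimate`s (all the same method) or a bare
#'   numeric vector of rates
#' @param method method label when `rates` is numeric
#' @return a `rate_summary` list: mean, sd, rsd_percent, n, method
#' @export
summarize_rates <- function(rates, method = NULL) {
  if (is.numeric(rates)) {
    vals <- rates
    method <- method %||% "unknown"
  } else {
    stopifnot(all(vapply(rates, inherits, logical(1), "rate_estimate")))
    methods <- vapply(rates, function(r) r$method, character(1))
    if (length(unique(methods)) != 1) {
      stop("all rates must come from the same method", call. = FALSE)
    }
    method <- methods[1]
    vals <- vapply(rates, function(r) r$rate, numeric(1))
  }
  if (length(vals) < 2) stop("at least 2 rates are required", call. = FALSE)
  m <- mean(vals)
  s <- stats::sd(vals)
  structure(list(mean = m, sd = s,
                 rsd_percent = if (m != 0) 100 * s / abs(m) else NA_real_,
                 n = length(vals), method = method),
            class = "rate_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rate_estimate <- function(rate, se, adj_r2, method, window) {
  structure(list(rate = rate, se = se, adj_r2 = adj_r2, method = method,
                 window = window),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s: %.4g umol/(day cm3 void)", x$method, x$rate))
  if (is.finite(x$se)) cat(sprintf(" (se %.3g)", x$se))
  if (is.finite(x$adj_r2)) cat(sprintf(", adj R2 %.3f", x$adj_r2))
  cat(sprintf(" [days %g-%g]\n", x$window[1], x$window[2]))
  invisible(x)
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("<rate_summary> %s: %.3f +/- %.3f umol/(day cm3), RSD %.0f%% (n = %d)\n",
              x$method, x$mean, x$sd, x$rsd_percent, x$n))
  invisible(x)
}
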
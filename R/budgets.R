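#' Cumulative sulfate supplied by porewater inflow
#'
#' Integrates a daily flow log against the inflow sulfate concentration
#' (rectangle rule, one rectangle per logged day). Missing days are an
#' error unless `fill = "zero"` treats them as no-flow days.
#'
#' @param flow_log data.frame with columns `day` (consecutive integers)
#'   and `ul_min` (mean flow that day, uL/min)
#' @param c_in inflow sulfate concentration, mM
#' @param fill `"error"` (default) or `"zero"` for missing days
#' @return total sulfate delivered, mmol
#' @export
cumulative_sulfate_supplied <- function(flow_log, c_in, fill = c("error", "zero")) {
  fill <- match.arg(fill)
  stopifnot(is.data.frame(flow_log), all(c("day", "ul_min") %in% names(flow_log)))
  assert_nonneg(flow_log$ul_min, "ul_min")
  assert_nonneg(c_in, "c_in")
  days <- sort(flow_log$day)
  expected <- seq(min(days), max(days))
  missing <- setdiff(expected, days)
  if (length(missing) && fill == "error") {
    stop("flow log is missing days: ", paste(utils::head(missing, 5), collapse = ", "),
         "; pass fill = \"zero\" to treat them as no-flow", call. = FALSE)
  }
  litres <- sum(flow_log$ul_min * 1440 * 1e-6)
  litres * c_in
}

#' Molar H2-to-sulfate supply ratios
#'
#' The electron-donor/acceptor balance of a run: moles of H2 supplied per
#' mole of sulfate, counting either porewater sulfate only
#' (`ratio_water`) or porewater plus gypsum sulfate (`ratio_total`).
#' Four moles of H2 are needed per mole of sulfate reduced, so ratios
#' below 4 mean sulfate is in stoichiometric excess.
#'
#' @param h2_total H2 supplied, mmol
#' @param sulfate_water sulfate delivered by porewater, mmol (> 0)
#' @param gypsum sulfate held in gypsum, mmol
#' @return list with raw ratios (`ratio_water`, `ratio_total`) and their
#'   1-decimal half-up display values (`display_water`, `display_total`)
#' @export
molar_ratios <- function(h2_total, sulfate_water, gypsum) {
  assert_nonneg(h2_total, "h2_total")
  assert_pos(sulfate_water, "sulfate_water")
  assert_nonneg(gypsum, "gypsum")
  rw <- h2_total / sulfate_water
  rt <- h2_total / (sulfate_water + gypsum)
  list(ratio_water = rw, ratio_total = rt,
       display_water = round_half_up(rw, 1),
       display_total = round_half_up(rt, 1))
}

#' Convert a sulfate-reduction rate to an H2-oxidation rate
#'
#' Hydrogenotrophic sulfate reduction consumes 4 mol H2 per mol sulfate
#' (4 H2 + SO4^2- + H+ -> HS- + 4 H2O), so the H2 rate is exactly four
#' times the sulfate rate.
#'
#' @param rate_so4 sulfate-reduction rate, umol/(day cm3)
#' @return H2-oxidation rate, umol/(day cm3)
#' @export
h2_rate_from_sulfate <- function(rate_so4) 4 * rate_so4

#' Convert a per-void-volume rate to a per-backfill-volume rate
#'
#' Volumetric rates are measured per cm3 of porewater-filled void; scaling
#' by the backfill porosity gives the rate per bulk volume of emplaced
#' backfill. Since umol/cm3 = mol/m3, the unit conversion is an identity.
#'
#' @param rate_void rate, umol/(day cm3 void)
#' @param porosity void fraction of the backfill, in (0, 1]. The default
#'   0.45 is the sand-bentonite porosity consistent with the published
#'   void-to-backfill rate conversions.
#' @return list with `rate` (mol/(day m3 backfill), unrounded) and
#'   `display` (1-decimal half-up)
#' @export
backfill_rate <- function(rate_void, porosity = 0.45) {
  assert_nonneg(rate_void, "rate_void")
  if (porosity <= 0 || porosity > 1) {
    stop("'porosity' must be in (0, 1]", call. = FALSE)
  }
  r <- rate_void * porosity
  list(rate = r, display = round_half_up(r, 1))
}

#' Repository scale-up parameters
#'
#' The gas inventory and geometry of the repository-scale extrapolation: a
#' production of `h2_inventory` moles of H2 over `horizon` years must be
#' consumed within `backfill_volume` m3 of gallery backfill.
#'
#' @param h2_inventory total H2 produced, mol (default 900e6)
#' @param horizon safety period, years (default 1000)
#' @param backfill_volume gallery backfill volume, m3 (default 390000)
#' @param porosity backfill void fraction (default 0.45)
#' @param days_per_year days per year (default 365.25, leap-inclusive;
#'   sensitivity to 365.0 is < 0.1 %)
#' @return an object of class `scaleup_params`
#' @export
scaleup_params <- function(h2_inventory = 900e6, horizon = 1000,
                           backfill_volume = 390000, porosity = 0.45,
                           days_per_year = 365.25) {
  assert_pos(h2_inventory, "h2_inventory")
  assert_pos(horizon, "horizon")
  assert_pos(backfill_volume, "backfill_volume")
  assert_pos(days_per_year, "days_per_year")
  if (porosity <= 0 || porosity > 1) {
    stop("'porosity' must be in (0, 1]", call. = FALSE)
  }
  structure(list(h2_inventory = h2_inventory, horizon = horizon,
                 backfill_volume = backfill_volume, porosity = porosity,
                 days_per_year = days_per_year),
            class = "scaleup_params")
}

#' Fraction of the backfill needed to consume the H2 inventory
#'
#' Converts the inventory to a constant daily production and asks what
#' share of the backfill, oxidising H2 at `rate_backfill`, would consume
#' it: `100 * (inventory / (horizon * days_per_year)) /
#' (rate_backfill * backfill_volume)`.
#'
#' @param scale a [scaleup_params()]
#' @param rate_backfill H2-oxidation rate, mol/(day m3 backfill) (> 0)
#' @return required backfill share, percent
#' @export
backfill_fraction_required <- function(scale, rate_backfill) {
  stopifnot(inherits(scale, "scaleup_params"))
  assert_pos(rate_backfill, "rate_backfill")
  daily <- scale$h2_inventory / (scale$horizon * scale$days_per_year)
  100 * daily / (rate_backfill * scale$backfill_volume)
}

#' Gas-mole balance of hydrogenotrophic methanogenesis
#'
#' 4 H2 + CO2 -> CH4 + 2 H2O consumes 5 moles of gas for every mole of
#' CH4 produced, a net removal of 4 gas moles: methanogenesis reduces
#' pressure despite producing gas.
#'
#' @param ch4 CH4 produced, mol (>= 0)
#' @return list: `ch4`, `gas_consumed` (= 5 ch4, mol) and
#'   `net_gas_change` (= -4 ch4, mol; negative = pressure-reducing)
#' @export
methanogenesis_gas_balance <- function(ch4) {
  assert_nonneg(ch4, "ch4")
  list(ch4 = ch4, gas_consumed = 5 * ch4, net_gas_change = -4 * ch4)
}

#' Classify an iron-to-sulfur atomic ratio by mineral stoichiometry
#'
#' Interprets Fe:S atomic ratios from elemental mapping of sulfur
#' hotspots against iron-sulfide stoichiometries: pyrite FeS2 (Fe:S =
#' 0.5) and mackinawite FeS (Fe:S = 1). Ratios within `tol` of the
#' targets are assigned to the nearer mineral (ties to the lower,
#' pyrite); below `0.5 - tol` is sulfur-excess, above `1 + tol` is
#' iron-excess. Boundary values assign to the lower class.
#'
#' @param fe_to_s Fe:S atomic ratio(s), >= 0
#' @param tol classification half-width (default 0.25)
#' @return character vector in `{"sulfur-excess", "pyrite-like",
#'   "mackinawite-like", "iron-excess"}`
#' @export
classify_fe_s_ratio <- function(fe_to_s, tol = 0.25) {
  assert_nonneg(fe_to_s, "fe_to_s")
  assert_pos(tol, "tol")
  out <- character(length(fe_to_s))
  lo <- 0.5 - tol
  hi <- 1 + tol
  for (i in seq_along(fe_to_s)) {
    r <- fe_to_s[i]
    out[i] <- if (r < lo) "sulfur-excess"
    else if (r > hi) "iron-excess"
    else if (abs(r - 0.5) <= abs(r - 1)) "pyrite-like"
    else "mackinawite-like"
  }
  out
}

#' Sulfide and iron budget of a run
#'
#' Closes the sulfide ledger of a simulated (or monitored) run: cumulative
#' sulfide produced by sulfate reduction, cumulative ferrous iron
#' delivered (initial pool plus inflow), and the sulfur bound as FeS,
#' which can never exceed the lesser of the two.
#'
#' @param sim a `reactor_sim`
#' @param fe_inflow_log optional data.frame (`day`, `ul_min`, `c_fe_uM`)
#'   overriding the simulated iron delivery; its day range must cover the
#'   simulated duration
#' @return list: `sulfide_produced` (mmol), `fe_delivered` (mmol),
#'   `fes_sulfur` (mmol)
#' @export
sulfide_iron_budget <- function(sim, fe_inflow_log = NULL) {
  stopifnot(inherits(sim, "reactor_sim"))
  cfg <- sim$config
  fe0 <- cfg$c0_fe / 1000 * cfg$v_voids / 1000
  if (is.null(fe_inflow_log)) {
    fe_in <- fe0 + sim$totals$in_fe
  } else {
    stopifnot(all(c("day", "ul_min", "c_fe_uM") %in% names(fe_inflow_log)))
    rng <- range(fe_inflow_log$day)
    if (rng[1] > 0 || rng[2] < cfg$duration - 1) {
      stop("'fe_inflow_log' does not cover the simulated duration", call. = FALSE)
    }
    fe_in <- fe0 + sum(fe_inflow_log$ul_min * 1440 * 1e-6 *
                         fe_inflow_log$c_fe_uM / 1000)
  }
  list(sulfide_produced = sim$totals$cons_so4,
       fe_delivered = fe_in,
       fes_sulfur = sim$totals$fes)
}

#' Table-style supply ledger for a set of reactors
#'
#' Assembles the electron donor/acceptor accounting for each reactor:
#' duration, sulfate delivered by water, gypsum inventory, total H2, and
#' the two molar H2:sulfate ratios (display-rounded to 1 decimal).
#'
#' @param reactors data.frame with columns `reactor`, `duration`,
#'   `sulfate_water` (mmol), `h2_total` (mmol)
#' @param gypsum gypsum sulfate per reactor, mmol (recycled; default 8.2)
#' @return data.frame ledger with ratio columns appended
#' @export
supply_ledger <- function(reactors, gypsum = 8.2) {
  stopifnot(all(c("reactor", "duration", "sulfate_water", "h2_total") %in%
                  names(reactors)))
  gypsum <- rep_len(gypsum, nrow(reactors))
  rw <- rt <- numeric(nrow(reactors))
  for (i in seq_len(nrow(reactors))) {
    r <- molar_ratios(reactors$h2_total[i], reactors$sulfate_water[i], gypsum[i])
    rw[i] <- r$display_water
    rt[i] <- r$display_total
  }
  cbind(reactors, gypsum = gypsum, ratio_water = rw, ratio_total = rt)
}
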
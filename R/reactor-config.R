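#' Reactor configuration
#'
#' Geometry, inflow chemistry, gypsum inventory and schedules of a
#' flow-through sand-bentonite reactor. Defaults emulate the monitored
#' microcosm reactors: a ~12 cm x 10 cm diameter cylinder (interior ~942
#' cm3) whose pore space (~420 cm3 at ~45 % porosity) is saturated with
#' sulfate-rich Opalinus Clay porewater (~15 mM sulfate), supplied by a
#' gravity-driven inflow of a few uL/min and a daily pulse of pure H2, with
#' ~8.2 mmol of sulfate held in bentonite gypsum.
#'
#' @param v_voids void (porewater-filled) volume, cm3
#' @param v_total reactor interior volume, cm3
#' @param c_in_sulfate inflow sulfate concentration, mM
#' @param c_in_fe inflow ferrous iron, uM
#' @param c0_sulfate initial (post-equilibration) dissolved sulfate, mM
#' @param c0_fe initial ferrous iron, uM
#' @param gypsum0 initial gypsum sulfate inventory, mmol
#' @param c_sat sulfate concentration at gypsum saturation, mM
#' @param duration experiment duration, days
#' @param flow_profile inflow rate, uL/min: a single number or a
#'   `data.frame(day, value)` of piecewise-constant regimes
#' @param h2_schedule daily H2 pulse, mmol/day: a single number or a
#'   `data.frame(day, value)`
#' @return an object of class `reactor_config`
#' @export
reactor_config <- function(v_voids = 420, v_total = 942,
                           c_in_sulfate = 15, c_in_fe = 30,
                           c0_sulfate = 15, c0_fe = 120,
                           gypsum0 = 8.2, c_sat = 20,
                           duration = 108,
                           flow_profile = 2, h2_schedule = 0.45) {
  for (nm in c("v_voids", "v_total", "duration")) {
    assert_pos(get(nm), nm)
  }
  for (nm in c("c_in_sulfate", "c_in_fe", "c0_sulfate", "c0_fe",
               "gypsum0", "c_sat")) {
    assert_scalar(get(nm), nm)
    assert_nonneg(get(nm), nm)
  }
  if (v_voids > v_total) {
    stop("'v_voids' must not exceed 'v_total'", call. = FALSE)
  }
  cfg <- list(
    v_voids = v_voids, v_total = v_total,
    c_in_sulfate = c_in_sulfate, c_in_fe = c_in_fe,
    c0_sulfate = c0_sulfate, c0_fe = c0_fe,
    gypsum0 = gypsum0, c_sat = c_sat,
    duration = duration,
    flow_profile = as_profile(flow_profile, "flow_profile"),
    h2_schedule = as_profile(h2_schedule, "h2_schedule")
  )
  structure(cfg, class = "reactor_config")
}

#' Kinetic parameters of the reactor model
#'
#' Rate constants for the simulated biogeochemistry. All rates are
#' volumetric with respect to void (porewater) volume. `k_h2` scales the
#' fraction of each day's H2 pulse that is bioavailable (1 = the whole
#' pulse); sulfate reduction and methanogenesis stop for the rest of the
#' day once that budget is spent. `so4_gate` encodes the competitive
#' exclusion of methanogens by sulfate reducers: methanogenesis switches on
#' only below this sulfate concentration.
#'
#' @param vmax_sr maximum volumetric sulfate-reduction rate, umol/(day cm3)
#' @param k_so4 sulfate half-saturation, mM
#' @param k_h2 bioavailable fraction of the daily H2 pulse, dimensionless
#' @param k_gyp gypsum dissolution rate constant, 1/day
#' @param vmax_meth maximum methanogenesis rate, umol CH4/(day cm3)
#' @param so4_gate sulfate threshold below which methanogenesis switches
#'   on, mM
#' @param growth logistic biomass scaling factor (1 = constant activity)
#' @return an object of class `kinetic_params`
#' @export
kinetic_params <- function(vmax_sr = 0.5, k_so4 = 0.3, k_h2 = 1,
                           k_gyp = 0.01, vmax_meth = 0.05,
                           so4_gate = 1, growth = 1) {
  for (nm in c("vmax_sr", "k_h2", "k_gyp", "vmax_meth", "so4_gate",
               "growth")) {
    assert_scalar(get(nm), nm)
    assert_nonneg(get(nm), nm)
  }
  assert_pos(k_so4, "k_so4")
  structure(list(vmax_sr = vmax_sr, k_so4 = k_so4, k_h2 = k_h2,
                 k_gyp = k_gyp, vmax_meth = vmax_meth,
                 so4_gate = so4_gate, growth = growth),
            class = "kinetic_params")
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config>\n")
  cat(sprintf("  voids %.0f cm3 of %.0f cm3 total; duration %g days\n",
              x$v_voids, x$v_total, x$duration))
  cat(sprintf("  sulfate: inflow %.1f mM, initial %.1f mM; gypsum %.1f mmol (sat %.1f mM)\n",
              x$c_in_sulfate, x$c0_sulfate, x$gypsum0, x$c_sat))
  cat(sprintf("  ferrous iron: inflow %.0f uM, initial %.0f uM\n",
              x$c_in_fe, x$c0_fe))
  cat(sprintf("  flow %s uL/min; H2 pulse %s mmol/day\n",
              paste(unique(x$flow_profile$value), collapse = "/"),
              paste(unique(x$h2_schedule$value), collapse = "/")))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  vmax_sr %.3g umol/(day cm3), k_so4 %.3g mM, k_h2 %.2f\n",
              x$vmax_sr, x$k_so4, x$k_h2))
  cat(sprintf("  k_gyp %.3g /day; vmax_meth %.3g umol/(day cm3), gate %.2g mM\n",
              x$k_gyp, x$vmax_meth, x$so4_gate))
  invisible(x)
}
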
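# Shared scenario builders for the test suite.

# Closed-system zero-order scenario: no flow, no gypsum, sulfate start high
# enough that weekly sampling over 8 weeks stays in the linear regime, H2
# pulse large enough never to limit. Nominal consumption 1.75 umol/(day cm3).
closed_zero_order <- function(duration = 56, vmax = 1.75, step = 0.02) {
  cfg <- reactor_config(v_voids = 420, v_total = 942,
                        c0_sulfate = 120, c_in_sulfate = 15,
                        c0_fe = 0, c_in_fe = 0,
                        gypsum0 = 0, duration = duration,
                        flow_profile = 0, h2_schedule = 10)
  kp <- kinetic_params(vmax_sr = vmax, k_so4 = 0.1, k_gyp = 0,
                       vmax_meth = 0, so4_gate = 0)
  simulate_reactor(cfg, kp, step = step)
}

# A short study-like run (inflow, gypsum, H2-limited kinetics) for cheap
# property checks.
study_like <- function(duration = 40, step = 0.02, ...) {
  cfg <- reactor_config(duration = duration, ...)
  simulate_reactor(cfg, kinetic_params(), step = step)
}

# Random-but-reproducible parameter draws for conservation sweeps.
random_scenario <- function(seed) {
  set.seed(seed)
  cfg <- reactor_config(
    duration = 60,
    c0_sulfate = runif(1, 10, 20),
    c0_fe = runif(1, 80, 120),
    gypsum0 = runif(1, 0, 10),
    flow_profile = runif(1, 0, 32),
    h2_schedule = runif(1, 0.2, 2)
  )
  kp <- kinetic_params(
    vmax_sr = runif(1, 0.2, 2),
    k_so4 = runif(1, 0.1, 1),
    k_gyp = runif(1, 0, 0.03),
    vmax_meth = runif(1, 0, 0.1),
    so4_gate = runif(1, 0, 2)
  )
  simulate_reactor(cfg, kp, step = 0.02, seed = seed)
}
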
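make_series <- function(day, conc, sd = 0, n = 3) {
  porewater_series(data.frame(day = day, analyte = "sulfate", mean = conc,
                              sd = sd, n = n))
}

test_that("a perfect line is recovered exactly", {
  s <- make_series(seq(0, 70, 7), 15 - 1.5 * seq(0, 70, 7) / 7 * 0.7)
  # slope -0.15 mM/day
  est <- linear_rate(s)
  expect_equal(est$rate, 0.15, tolerance = 1e-12)
  expect_equal(est$adj_r2, 1)
  expect_lt(est$se, 1e-10)

  const <- make_series(c(0, 7, 14, 21), rep(15, 4))
  expect_equal(linear_rate(const)$rate, 0)
})

test_that("the slope equals the closed-form normal-equations solution", {
  set.seed(11)
  day <- seq(0, 98, 7)
  conc <- 20 - 0.12 * day + rnorm(length(day), 0, 0.5)
  est <- linear_rate(make_series(day, conc))
  # independent oracle: normal equations
  sxx <- sum((day - mean(day))^2)
  sxy <- sum((day - mean(day)) * (conc - mean(conc)))
  expect_equal(est$rate, -sxy / sxx, tolerance = 1e-12)
  resid <- conc - (mean(conc) + sxy / sxx * (day - mean(day)))
  se_oracle <- sqrt(sum(resid^2) / (length(day) - 2) / sxx)
  expect_equal(est$se, se_oracle, tolerance = 1e-10)
})

test_that("the rate is invariant to time shifts and concentration offsets", {
  set.seed(12)
  day <- seq(0, 70, 7)
  conc <- 18 - 0.2 * day + rnorm(length(day), 0, 0.3)
  base <- linear_rate(make_series(day, conc))$rate
  expect_equal(linear_rate(make_series(day + 13, conc))$rate, base)
  expect_equal(linear_rate(make_series(day, conc + 5))$rate, base)
})

test_that("degenerate regression inputs are rejected", {
  expect_error(linear_rate(make_series(c(0, 7), c(15, 14))), "3 sulfate")
  flat_days <- make_series(c(0, 7, 14), c(15, 14, 13))[c(1, 1, 1), ]
  expect_error(linear_rate(flat_days), "zero variance")
})

test_that("mass balance reproduces direct arithmetic on stated inputs", {
  inp <- mass_balance_inputs(
    v_in_tot = 0.1, c_in = 15, n_gypsum = 1.0,
    weekly_outflow = data.frame(volume = c(0.04, 0.04), c_out = c(10, 10)),
    v_voids = 400, c_out_end = 3, days = 100)
  est <- mass_balance_rate(inp)
  expect_equal(est$budget_mmol, 1.5 + 1.0 - 0.8 - 1.2, tolerance = 1e-12)
  expect_equal(est$rate, 0.0125, tolerance = 1e-12)
})

test_that("a fully depleted closed system gives depletion over time", {
  # initial fill counts as injected water at the starting concentration
  inp <- mass_balance_inputs(
    v_in_tot = 0.4, c_in = 15, n_gypsum = 0,
    weekly_outflow = NULL, v_voids = 400, c_out_end = 0, days = 100)
  expect_equal(mass_balance_rate(inp)$rate, 0.15, tolerance = 1e-12)
})

test_that("mass balance on simulator bookkeeping matches the truth", {
  sim <- simulate_reactor(reactor_config(duration = 60), kinetic_params(),
                          step = 0.02)
  mb <- mass_balance_rate(mass_balance_inputs_from_sim(sim))
  expect_lt(abs(mb$rate - sim$truth) / sim$truth, 0.01)
})

test_that("rebinning the outflow does not change the balance when concentration is constant in bins", {
  mk <- function(vols) {
    mass_balance_rate(mass_balance_inputs(
      v_in_tot = 1, c_in = 15, n_gypsum = 2,
      weekly_outflow = data.frame(volume = vols, c_out = rep(8, length(vols))),
      v_voids = 400, c_out_end = 4, days = 80))$rate
  }
  expect_equal(mk(c(0.8)), mk(c(0.2, 0.2, 0.2, 0.2)))
  expect_equal(mk(c(0.8)), mk(c(0.5, 0.3)))
})

test_that("negative budgets are flagged, invalid inputs rejected", {
  inp <- mass_balance_inputs(v_in_tot = 0.01, c_in = 1, n_gypsum = 0,
                             weekly_outflow = NULL, v_voids = 400,
                             c_out_end = 10, days = 10)
  expect_warning(est <- mass_balance_rate(inp), "accumulation")
  expect_true(est$accumulation)
  expect_error(mass_balance_inputs(0.1, 15, 0, NULL, v_voids = 0,
                                   c_out_end = 1, days = 10), "v_voids")
  expect_error(mass_balance_inputs(
    0.1, 15, 0, data.frame(volume = 5, c_out = 1), 400, 1, 10), "exceed")
})

test_that("a piecewise series splits into exact per-window rates", {
  day <- seq(0, 98, 7)
  conc <- ifelse(day <= 49, 120 - 2 * day, 120 - 2 * 49)
  est <- windowed_rate(make_series(day, conc), breakpoint = 49)
  expect_equal(est$before$rate, 2, tolerance = 1e-12)
  expect_equal(est$after$rate, 0, tolerance = 1e-12)

  # each window matches an independent per-window least-squares fit
  set.seed(4)
  conc2 <- conc + rnorm(length(day), 0, 0.4)
  s2 <- make_series(day, conc2)
  w <- windowed_rate(s2, 49)
  for (side in list(c(0, 49), c(56, 98))) {
    sel <- day >= side[1] & day <= side[2]
    sxx <- sum((day[sel] - mean(day[sel]))^2)
    sxy <- sum((day[sel] - mean(day[sel])) * (conc2[sel] - mean(conc2[sel])))
    ref <- -sxy / sxx
    got <- if (side[1] == 0) w$before$rate else w$after$rate
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("a degenerate split keeps the full-series fit and drops the empty side", {
  day <- seq(0, 42, 7)
  s <- make_series(day, 15 - 0.1 * day)
  expect_warning(w <- windowed_rate(s, max(day)), "fewer than 3")
  expect_equal(w$before$rate, linear_rate(s)$rate)
  expect_true(is.na(w$after$rate))
  expect_error(windowed_rate(s, 99), "within the observed")
})

test_that("rate summaries use the sample SD convention", {
  s <- summarize_rates(c(1.548, 1.920, 1.630, 1.911), method = "linear_regression")
  expect_equal(round(s$mean, 3), 1.752)
  expect_equal(round(s$sd, 3), 0.191)
  expect_equal(round(s$rsd_percent), 11)

  s2 <- summarize_rates(c(0.35, 0.27, 0.62, 0.52), method = "mass_balance")
  expect_equal(round(s2$mean, 2), 0.44)

  s3 <- summarize_rates(rep(1.3, 4), method = "mass_balance")
  expect_equal(s3$sd, 0)
  expect_equal(s3$rsd_percent, 0)
})

test_that("mixed-method summaries are rejected", {
  a <- linear_rate(make_series(c(0, 7, 14), c(15, 14, 13)))
  b <- mass_balance_rate(mass_balance_inputs(0.4, 15, 0, NULL, 400, 1, 100))
  expect_error(summarize_rates(list(a, b)), "same method")
  expect_error(summarize_rates(1.5), "at least 2")
})

test_that("noiseless closed-system estimators agree with the truth within 1 %", {
  sim <- closed_zero_order()
  obs <- sample_observations(sim, seq(0, 56, 7),
                             noise_sd = c(sulfate = 0, sulfide = 0, fe = 0))
  lin <- linear_rate(obs)
  mb <- mass_balance_rate(mass_balance_inputs_from_sim(sim))
  expect_lt(abs(lin$rate - sim$truth) / sim$truth, 0.01)
  expect_lt(abs(mb$rate - sim$truth) / sim$truth, 0.01)
  expect_lt(abs(lin$rate - mb$rate) / mb$rate, 0.01)
})
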
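test_that("cumulative sulfate supply integrates the flow log", {
  log <- data.frame(day = 1:100, ul_min = 4)
  expect_equal(cumulative_sulfate_supplied(log, 15), 8.64, tolerance = 1e-12)
  expect_equal(cumulative_sulfate_supplied(data.frame(day = 1:10, ul_min = 0), 15), 0)

  gap <- data.frame(day = c(1, 2, 4), ul_min = 2)
  expect_error(cumulative_sulfate_supplied(gap, 15), "missing days")
  expect_equal(cumulative_sulfate_supplied(gap, 15, fill = "zero"),
               3 * 2 * 1440e-6 * 15)
})

test_that("a daily-constant profile matches a finer-grained integration", {
  set.seed(21)
  flow <- data.frame(day = 1:60, ul_min = round(runif(60, 0, 32), 1))
  coarse <- cumulative_sulfate_supplied(flow, 15)
  # oracle: 10 sub-steps per day, piecewise-constant within days
  fine <- sum(rep(flow$ul_min, each = 10) * (1440 / 10) * 1e-6) * 15
  expect_equal(coarse, fine, tolerance = 1e-10)
})

test_that("molar supply ratios reproduce the printed ledger entries", {
  r1 <- molar_ratios(49.1, 10.1, 8.2)
  expect_equal(r1$display_water, 4.9)
  expect_equal(r1$display_total, 2.7)
  r3 <- molar_ratios(32.6, 16.1, 8.2)
  expect_equal(r3$display_water, 2.0)
  expect_equal(r3$display_total, 1.3)
  nogyp <- molar_ratios(4.0, 1.0, 0.0)
  expect_equal(nogyp$ratio_water, 4.0)
  expect_equal(nogyp$ratio_total, 4.0)
  expect_error(molar_ratios(1, 0, 1), "sulfate_water")
})

test_that("the total ratio never exceeds the water ratio", {
  set.seed(31)
  for (i in 1:50) {
    h2 <- runif(1, 1, 60)
    sw <- runif(1, 1, 30)
    g <- runif(1, 0, 10)
    r <- molar_ratios(h2, sw, g)
    expect_lte(r$ratio_total, r$ratio_water)
    if (g > 0) expect_lt(r$ratio_total, r$ratio_water)
  }
})

test_that("the H2 conversion is exact 4x stoichiometry and linear", {
  expect_equal(h2_rate_from_sulfate(1.752), 7.008)
  expect_equal(round(h2_rate_from_sulfate(0.44), 2), 1.76)
  expect_equal(h2_rate_from_sulfate(0), 0)
  a <- 0.37; b <- 1.21
  expect_equal(h2_rate_from_sulfate(a + b),
               h2_rate_from_sulfate(a) + h2_rate_from_sulfate(b))
})

test_that("void-to-backfill conversion scales by porosity", {
  expect_equal(backfill_rate(2.5, porosity = 1)$rate, 2.5)
  expect_equal(backfill_rate(7, 0.45)$display, 3.2)
  expect_equal(backfill_rate(2, 0.45)$display, 0.9)
  expect_equal(backfill_rate(0, 0.45)$rate, 0)
  expect_error(backfill_rate(1, porosity = 0), "porosity")
  expect_error(backfill_rate(1, porosity = 1.2), "porosity")
})

test_that("the repository H2 inventory needs under 1 % of the backfill", {
  sc <- scaleup_params(h2_inventory = 900e6, horizon = 1000,
                       backfill_volume = 390000)
  frac <- backfill_fraction_required(sc, 0.9)
  expect_lt(frac, 1)
  expect_equal(round(frac, 2), 0.70)
  # inverse proportionality in rate and volume
  expect_equal(backfill_fraction_required(sc, 1.8), frac / 2)
  sc2 <- scaleup_params(backfill_volume = 2 * 390000)
  expect_equal(backfill_fraction_required(sc2, 0.9), frac / 2)
  expect_error(backfill_fraction_required(sc, 0), "rate_backfill")
})

test_that("methanogenesis removes four net gas moles per CH4", {
  g <- methanogenesis_gas_balance(1)
  expect_equal(g$gas_consumed, 5)
  expect_equal(g$net_gas_change, -4)
  expect_equal(methanogenesis_gas_balance(0)$gas_consumed, 0)
  g2 <- methanogenesis_gas_balance(2)
  expect_equal(g2$gas_consumed, 10)
  expect_equal(g2$net_gas_change, -8)
  expect_error(methanogenesis_gas_balance(-1), "ch4")
})

test_that("Fe:S ratios classify by nearest mineral stoichiometry", {
  expect_equal(classify_fe_s_ratio(0.45), "pyrite-like")
  expect_equal(classify_fe_s_ratio(0.17), "sulfur-excess")
  expect_equal(classify_fe_s_ratio(1.0), "mackinawite-like")
  # boundaries assign deterministically to the lower class
  expect_equal(classify_fe_s_ratio(0.25), "pyrite-like")
  expect_equal(classify_fe_s_ratio(0.75), "pyrite-like")
  expect_equal(classify_fe_s_ratio(1.25), "mackinawite-like")
  expect_equal(classify_fe_s_ratio(0.2499999), "sulfur-excess")
  expect_equal(classify_fe_s_ratio(1.2500001), "iron-excess")
  expect_error(classify_fe_s_ratio(-0.1), "fe_to_s")
  # piecewise-constant: monotone label sequence over a grid
  labels <- classify_fe_s_ratio(seq(0, 2, by = 0.05))
  expect_equal(rle(labels)$values,
               c("sulfur-excess", "pyrite-like", "mackinawite-like",
                 "iron-excess"))
})

test_that("the sulfide-iron budget respects its bounds", {
  # no iron at all: no FeS regardless of sulfide
  sim0 <- simulate_reactor(
    reactor_config(duration = 20, c0_fe = 0, c_in_fe = 0, flow_profile = 2),
    kinetic_params(vmax_sr = 0.5), step = 0.02)
  b0 <- sulfide_iron_budget(sim0)
  expect_equal(b0$fes_sulfur, 0)
  expect_gt(b0$sulfide_produced, 0)

  # excess sulfide: all delivered iron ends up as FeS
  sim1 <- simulate_reactor(
    reactor_config(duration = 40, c0_fe = 120, c_in_fe = 30, flow_profile = 4),
    kinetic_params(vmax_sr = 0.8), step = 0.02)
  b1 <- sulfide_iron_budget(sim1)
  expect_lte(b1$fes_sulfur, min(b1$sulfide_produced, b1$fe_delivered) + 1e-9)
  # nearly all iron is scavenged (a little leaves in the outflow early on)
  expect_gt(b1$fes_sulfur / b1$fe_delivered, 0.9)

  # no sulfate reduction: no sulfide
  sim2 <- simulate_reactor(
    reactor_config(duration = 20), kinetic_params(vmax_sr = 0), step = 0.02)
  expect_equal(sulfide_iron_budget(sim2)$sulfide_produced, 0)

  expect_error(
    sulfide_iron_budget(sim2, data.frame(day = 5:10, ul_min = 1, c_fe_uM = 30)),
    "cover")
})

test_that("the supply ledger assembles printed inputs with display ratios", {
  reactors <- data.frame(reactor = c(1, 3), duration = c(108, 73),
                         sulfate_water = c(10.1, 16.1),
                         h2_total = c(49.1, 32.6))
  led <- supply_ledger(reactors)
  expect_equal(led$ratio_water, c(4.9, 2.0))
  expect_equal(led$ratio_total, c(2.7, 1.3))
})
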
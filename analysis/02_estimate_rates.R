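#!/usr/bin/env Rscript

# Estimates the sulfate-reduction rate of each simulated reactor with both
# estimators - zero-order linear regression on the weekly sulfate series,
# and the global mass balance over water, gypsum and outflow budgets - and
# compares them with the simulated ground truth. Also demonstrates the
# windowed estimator on reactor 3's flow-regime change. Writes a rate table
# in the two-method layout plus cross-reactor summaries.

library(h2sink)

ids <- c("r1", "r2", "r3", "r4")
rows <- list()
lin_rates <- mb_rates <- truths <- numeric(0)

for (id in ids) {
  obs <- read_porewater(file.path("results", paste0("observations_", id, ".csv")))
  side <- yaml::read_yaml(file.path("results", paste0("truth_", id, ".yaml")))

  lin <- linear_rate(obs)
  mbi <- mass_balance_inputs(
    v_in_tot = side$v_in_tot, c_in = side$c_in_eff, n_gypsum = side$n_gypsum,
    weekly_outflow = data.frame(volume = unlist(side$weekly_volume),
                                c_out = unlist(side$weekly_c_out)),
    v_voids = side$v_voids, c_out_end = side$c_out_end, days = side$duration)
  mb <- mass_balance_rate(mbi)

  rows[[id]] <- data.frame(
    reactor = id, lin_rate = lin$rate, lin_se = lin$se, lin_adj_r2 = lin$adj_r2,
    mb_rate = mb$rate, truth = side$truth)
  lin_rates <- c(lin_rates, lin$rate)
  mb_rates <- c(mb_rates, mb$rate)
  truths <- c(truths, side$truth)

  cat(sprintf(
    "%s: linear %.3f (se %.3f, adj R2 %.3f) | mass balance %.3f | truth %.3f umol/(day cm3)\n",
    id, lin$rate, lin$se, lin$adj_r2, mb$rate, side$truth))
}

tab <- do.call(rbind, rows)
write_porewater(tab, "results/rate_table.csv")

lin_sum <- summarize_rates(lin_rates, method = "linear_regression")
mb_sum <- summarize_rates(mb_rates, method = "mass_balance")
cat(sprintf("\nCross-reactor averages: linear %.3f +/- %.3f (RSD %.0f%%), mass balance %.3f +/- %.3f\n",
            lin_sum$mean, lin_sum$sd, lin_sum$rsd_percent,
            mb_sum$mean, mb_sum$sd))
cat(sprintf("Mass balance tracks the truth (mean |error| %.2f%%); the linear fit reads the net\n",
            100 * mean(abs(mb_rates - truths) / truths)))
cat("outlet decline only, so it underestimates consumption whenever inflow and gypsum resupply sulfate.\n")

# reactor 3: the inflow step at day 57 splits the series into two regimes
obs3 <- read_porewater("results/observations_r3.csv")
w <- windowed_rate(obs3, breakpoint = 49)
cat(sprintf("\nReactor 3 windowed rates: days 0-49 %.3f, days 49-73 %.3f umol/(day cm3)\n",
            w$before$rate, w$after$rate))
cat("(the high-flow window resupplies sulfate faster than it is consumed, so the\napparent outlet-decline rate drops or turns negative)\n")

write_porewater(data.frame(
  method = c("linear_regression", "mass_balance"),
  mean = c(lin_sum$mean, mb_sum$mean),
  sd = c(lin_sum$sd, mb_sum$sd),
  rsd_percent = c(lin_sum$rsd_percent, mb_sum$rsd_percent)),
  "results/rate_summary.csv")
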
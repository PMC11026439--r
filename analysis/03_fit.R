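#!/usr/bin/env Rscript
# Fit the before/after Bayesian driver regressions for every qualifying
# stock and apply the R2 / convergence retention filter. Uses the regional
# temperature extracted from the gridded field for the stock that has one,
# and each stock's own annual series otherwise. The reduced desk profile
# runs 4 chains x 2,000 iterations unthinned (the Gibbs backend's draws are
# near-independent, and 1,000 retained draws per chain keep the split-Rhat
# diagnostic from tripping its strict 1.01 threshold on sampling noise
# alone); pass "full" as the first argument for the 10,000-iteration,
# thin-10 reference protocol.

library(collapseshift)

args <- commandArgs(trailingOnly = TRUE)
profile <- if (length(args) && args[[1]] == "full") {
  mcmc_config(seed = 7L)
} else mcmc_config(n_iterations = 2000L, thin = 1L, seed = 7L)

cohort <- read_cohort("results/cohort")

fits <- list()
summaries <- list()
for (i in seq_along(cohort$stocks)) {
  st <- cohort$stocks[[i]]
  cw <- check_collapse(st)
  if (!cw$qualifies) next
  sl <- split_periods(st, cw)
  for (per in c("before", "after")) {
    ds <- build_dataset(sl[[per]])
    cfg <- profile
    cfg$seed <- profile$seed + 2L * i + (per == "after")
    fit <- fit_period_model(ds, cfg)
    fits[[st$stock_id]][[per]] <- fit
    qs <- apply(fit$draws, 2, quantile, c(0.05, 0.5, 0.95))
    summaries[[length(summaries) + 1L]] <- data.frame(
      stock_id = st$stock_id, period = per,
      parameter = colnames(fit$draws),
      q05 = qs[1, ], median = qs[2, ], q95 = qs[3, ],
      rhat = fit$rhat[colnames(fit$draws)],
      r2_median = fit$r2_median, vif_max = max(vif(ds)),
      row.names = NULL)
  }
}

fit_tbl <- do.call(rbind, summaries)
write.csv(fit_tbl, "results/fit_summaries.csv", row.names = FALSE)
saveRDS(fits, "results/fits.rds")   # scratch object for 04/05

flt <- filter_stocks(fits)
write.csv(flt$log, "results/retention.csv", row.names = FALSE)
cat(sprintf("fitted %d stocks; retained %d (median R2 >= 0.2 both periods, all Rhat <= 1.01)\n",
            length(fits), length(flt$retained)))
cat(sprintf("max VIF across datasets: %.2f\n", max(fit_tbl$vif_max)))
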
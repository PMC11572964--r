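#!/usr/bin/env Rscript
# Step 4 — whole-city prediction and canopy-goal inversion.
#
# Evaluates the pooled power law at the largest analytical-unit size
# (the planning-relevant "whole-city" scale) and inverts the predicted
# cooling efficiency into the percent canopy increase required for a
# 1.5 degC land-surface-temperature reduction.

suppressPackageStartupMessages(library(canopycooler))

fit_json <- jsonlite::read_json("results/fits/pooled_fit.json",
                                simplifyVector = TRUE)
# rebuild a fit object carrying the log-log band machinery
dates <- read.csv("results/sim/weather.csv")
per_date_est <- lapply(dates$date_id, function(d) {
  estimate_all(read_unit_tables(file.path("results/sim", d)))
})
pooled <- pool_fits(per_date_est)
stopifnot(abs(pooled$beta - fit_json$beta) < 1e-12)

s_city <- max(pooled$s_range)
pr <- predict_ce(pooled, s_city)
goal <- utc_goal(pr$ce_city, pr$ce_ci, delta_t_target = 1.5,
                 s_city_m = s_city)
print(goal)
jsonlite::write_json(unclass(goal), "results/prediction.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf(
  "adding 1%% canopy city-wide cools ~%.2f degC; a %.2f%% increase meets 1.5 degC",
  pr$ce_city, goal$utc_goal_pct))
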
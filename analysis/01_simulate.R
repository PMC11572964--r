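#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# Two kinds of input stand in for the satellite/aerial imagery:
#   (a) one raster pair (LST + canopy) whose canopy-temperature coupling
#       has a local and a neighbourhood-smoothed component, so the
#       estimated cooling efficiency grows with unit size, and
#   (b) eight "summer dates" of per-scale unit samples whose true
#       scaling exponent increases linearly with that date's air
#       temperature, the pattern reported for the arid-city case.
# Everything is written under results/sim/ for the later steps.

suppressPackageStartupMessages(library(canopycooler))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## (a) the raster pair: 60 x 60 base pixels of 120 m (a 7.2 km square)
rcfg <- raster_sim_config(n_rows = 60, n_cols = 60, pixel_size = 120,
                          canopy_corr_range = 600,
                          canopy_cover_target = 0.3,
                          local_effect = 5, neighborhood_effect = 5,
                          neighborhood_range = 600, noise_sd = 0.5,
                          seed = 20240801)
pair <- simulate_raster_pair(rcfg)
write_simulation(pair, file.path(out, "raster"), config = rcfg)
message(sprintf("raster pair: %d x %d px, realized cover %.3f",
                nrow(pair$lst$values), ncol(pair$lst$values),
                mean(pair$canopy$values)))

## (b) eight dates whose exponent tracks air temperature
dates <- data.frame(
  date_id = sprintf("d%02d", 1:8),
  air_temp_c = c(21.5, 23.0, 24.5, 26.0, 27.5, 29.0, 31.0, 33.0),
  wind_ms = c(3.1, 2.6, 2.9, 2.2, 1.8, 1.6, 1.2, 0.9),
  rel_humidity_pct = c(62, 58, 55, 50, 46, 41, 35, 30))
dates$vpd_hpa <- compute_vpd(dates$air_temp_c, dates$rel_humidity_pct)
dates$beta_true <- 0.04 + 0.004 * (dates$air_temp_c - 20)
dates$k_true <- 0.10

set.seed(20240802)
date_seeds <- sample.int(.Machine$integer.max, nrow(dates))
for (i in seq_len(nrow(dates))) {
  cfg <- tabular_sim_config(k = dates$k_true[i], beta = dates$beta_true[i],
                            scales = seq(120, 2760, by = 240),
                            n_per_scale = 500, noise_sd = 0.5,
                            seed = date_seeds[i])
  write_simulation(simulate_unit_tables(cfg),
                   file.path(out, dates$date_id[i]), config = cfg)
}
write.csv(dates, file.path(out, "weather.csv"), row.names = FALSE)
message(sprintf("wrote %d dates with true exponents %.3f..%.3f",
                nrow(dates), min(dates$beta_true), max(dates$beta_true)))
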
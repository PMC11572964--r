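#!/usr/bin/env Rscript
# Step 5 — weather dependence of the scaling exponent.
#
# Correlates the per-date fitted exponents with air temperature, wind
# speed, relative humidity, and vapor pressure deficit. In the
# generating model the exponent rises linearly with air temperature, so
# temperature (and the temperature-driven VPD) should correlate
# positively and humidity negatively.

suppressPackageStartupMessages(library(canopycooler))

per_date <- read.csv("results/fits/per_date_fits.csv")
weather <- read.csv("results/sim/weather.csv")

res <- correlate_exponents(
  data.frame(date_id = per_date$date_id, beta = per_date$beta_hat),
  weather)
write.csv(res, "results/weather_correlations.csv", row.names = FALSE)
print(res, digits = 3)
message(sprintf(
  "exponent vs air temperature: r = %.2f (p = %.2g), slope = %.4f per degC",
  res$r[res$covariate == "air_temp_c"],
  res$p_two_tailed[res$covariate == "air_temp_c"],
  res$slope[res$covariate == "air_temp_c"]))
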
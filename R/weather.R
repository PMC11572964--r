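#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Saturation vapor pressure by the Magnus approximation with the
#' WMO-standard coefficients,
#' `es = 6.112 * exp(17.62 * T / (243.12 + T))` hPa, and
#' `vpd = es * (1 - RH / 100)`. At 100% humidity the deficit is zero; at
#' 0% it equals the saturation pressure itself.
#'
#' @param air_temp_c Air temperature (deg C); vectorized.
#' @param rel_humidity_pct Relative humidity in `[0, 100]`; vectorized.
#' @return VPD in hPa.
#' @export
compute_vpd <- function(air_temp_c, rel_humidity_pct) {
  if (any(!is.finite(rel_humidity_pct)) ||
      any(rel_humidity_pct < 0 | rel_humidity_pct > 100)) {
    stop_config("`rel_humidity_pct` must lie in [0, 100]",
                field = "rel_humidity_pct")
  }
  es <- 6.112 * exp(17.62 * air_temp_c / (243.12 + air_temp_c))
  es * (1 - rel_humidity_pct / 100)
}

#' Relate per-date scaling exponents to weather covariates
#'
#' For each weather covariate (air temperature, wind speed, relative
#' humidity, VPD), computes the Pearson correlation with the per-date
#' scaling exponents, its two-tailed p-value via the t transform with
#' `n - 2` degrees of freedom, and the OLS slope of exponent on
#' covariate. VPD is computed by [compute_vpd()] when absent from the
#' records.
#'
#' @param betas `data.frame` with columns `date_id` and `beta` (one
#'   fitted scaling exponent per date).
#' @param records `data.frame` of weather records with columns
#'   `date_id`, `air_temp_c`, `wind_ms`, `rel_humidity_pct`, and
#'   optionally `vpd_hpa`.
#' @return `data.frame` with one row per covariate: `covariate`, `r`,
#'   `p_two_tailed`, `slope`, `n_dates`.
#' @export
correlate_exponents <- function(betas, records) {
  stopifnot(is.data.frame(betas), is.data.frame(records))
  missing_ids <- setdiff(betas$date_id, records$date_id)
  if (length(missing_ids) > 0) {
    stop_compute(sprintf(
      "weather records missing for date(s): %s",
      paste(missing_ids, collapse = ", ")),
      class = "canopycooler_join_error")
  }
  merged <- merge(betas, records, by = "date_id")
  n <- nrow(merged)
  if (n < 3L) {
    stop_compute(sprintf("need >= 3 matched dates, got %d", n),
                 class = "canopycooler_join_error")
  }
  if (is.null(merged$vpd_hpa)) {
    merged$vpd_hpa <- compute_vpd(merged$air_temp_c,
                                  merged$rel_humidity_pct)
  }
  covs <- c(air_temp_c = "air_temp_c", wind_ms = "wind_ms",
            rel_humidity_pct = "rel_humidity_pct", vpd_hpa = "vpd_hpa")
  rows <- lapply(covs, function(v) {
    ct <- stats::cor.test(merged$beta, merged[[v]], method = "pearson")
    sl <- unname(stats::coef(stats::lm(merged$beta ~ merged[[v]]))[2])
    data.frame(covariate = v, r = unname(ct$estimate),
               p_two_tailed = ct$p.value, slope = sl, n_dates = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
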
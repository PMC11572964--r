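#' Estimate cooling efficiency at one scale
#'
#' Cooling efficiency (CE) at a scale is the absolute value of the OLS
#' slope from the simple regression of unit-mean LST on unit percent
#' canopy cover, with a free intercept. A positive (warming) slope is
#' unusual but retained as its absolute value with a warning and
#' `slope_sign = "positive"`, since CE is defined through the magnitude
#' of the coefficient. A robust (HC3) standard-error option exists but
#' is off by default; the canonical analysis uses plain OLS.
#'
#' @param table A unit table (columns `ptree_pct`, `lst_mean_c`;
#'   attribute `scale_m`).
#' @param robust_se Use sandwich HC3 standard errors for `se_slope` and
#'   `p_slope` instead of the classical OLS ones.
#' @return A one-row `data.frame` of class `ce_estimate`: `scale_m`,
#'   `ce` (deg C per %UTC), `slope_sign`, `intercept_c`, `se_slope`,
#'   `r2`, `p_slope`, `n_units`.
#' @export
estimate_ce <- function(table, robust_se = FALSE) {
  s <- attr(table, "scale_m")
  if (is.null(s)) s <- table$scale_m[1]
  n <- nrow(table)
  if (is.null(n) || n < 3L) {
    stop_compute(sprintf(
      "scale %g m: need >= 3 units for CE estimation, got %d", s,
      if (is.null(n)) 0L else n), class = "canopycooler_estimation_error")
  }
  if (stats::var(table$ptree_pct) == 0) {
    stop_compute(sprintf(
      "scale %g m: zero Ptree variance, CE slope is unidentified", s),
      class = "canopycooler_estimation_error")
  }
  fit <- stats::lm(lst_mean_c ~ ptree_pct, data = table)
  cf <- summary(fit)$coefficients
  slope <- cf["ptree_pct", "Estimate"]
  if (robust_se) {
    vr <- sandwich::vcovHC(fit, type = "HC3")["ptree_pct", "ptree_pct"]
    se <- sqrt(vr)
    tval <- slope / se
    p <- 2 * stats::pt(abs(tval), df = n - 2L, lower.tail = FALSE)
  } else {
    se <- cf["ptree_pct", "Std. Error"]
    p <- cf["ptree_pct", "Pr(>|t|)"]
  }
  if (slope > 0) {
    warning(sprintf(
      "scale %g m: positive (warming) LST~Ptree slope %.4g; CE reported as |slope|",
      s, slope))
  }
  out <- data.frame(
    scale_m = s, ce = abs(slope),
    slope_sign = if (slope > 0) "positive" else "negative",
    intercept_c = cf["(Intercept)", "Estimate"],
    se_slope = se, r2 = summary(fit)$r.squared, p_slope = p,
    n_units = n
  )
  class(out) <- c("ce_estimate", "data.frame")
  out
}

#' Estimate cooling efficiency at every scale
#'
#' Runs [estimate_ce()] on each unit table, skipping (with a warning)
#' scales that fail its preconditions — too few units or a degenerate
#' design — and returning the surviving estimates ordered by scale.
#'
#' @param tables List of unit tables from one raster pair / date.
#' @param robust_se Passed to [estimate_ce()].
#' @return A `data.frame` with one row per usable scale (columns as
#'   [estimate_ce()]).
#' @export
estimate_all <- function(tables, robust_se = FALSE) {
  rows <- list()
  for (tab in tables) {
    est <- tryCatch(
      estimate_ce(tab, robust_se = robust_se),
      canopycooler_estimation_error = function(e) {
        warning(sprintf("skipping scale: %s", conditionMessage(e)))
        NULL
      })
    if (!is.null(est)) rows[[length(rows) + 1L]] <- est
  }
  if (length(rows) < 3L) {
    stop_compute(sprintf(
      "only %d scale(s) yielded a CE estimate; >= 3 are required for the power-law fit",
      length(rows)), class = "canopycooler_pipeline_error")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$scale_m), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ce_estimate", "data.frame")
  out
}
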
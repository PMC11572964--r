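#' Predict cooling efficiency at the whole-city scale
#'
#' Evaluates a fitted power law at an evaluation size `s_city_m`
#' (typically the largest aggregated scale, which is treated as the
#' planning-relevant "whole-city" scale): `ce_city = k * s_city^beta`.
#' The confidence interval is the mean-response band of the log-log
#' regression at `ln(s_city)`, exponentiated; for direct-space fits the
#' delta-method band from the asymptotic covariance is used. Sizes
#' beyond the fitted scale range are allowed but flagged as
#' extrapolation with a warning.
#'
#' Quadratic-form fits are refused: extrapolating a concave quadratic
#' beyond the fitted range is not meaningful, and within the range the
#' caller should evaluate the quadratic explicitly.
#'
#' @param fit A power-form `scaling_fit`.
#' @param s_city_m Evaluation size in the fit's S unit, > 0.
#' @return List with `ce_city` (deg C per %UTC) and `ce_ci` (95% band).
#' @export
predict_ce <- function(fit, s_city_m) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (fit$model_form != "power") {
    stop_compute(paste(
      "whole-city prediction requires a power-form fit; evaluate the",
      "quadratic explicitly within its fitted range instead"),
      class = "canopycooler_prediction_error")
  }
  if (!is.numeric(s_city_m) || length(s_city_m) != 1L || s_city_m <= 0) {
    stop_config("`s_city_m` must be a single positive size",
                field = "s_city_m")
  }
  if (s_city_m < fit$s_range[1] || s_city_m > fit$s_range[2]) {
    warning(sprintf(
      "s_city = %g lies outside the fitted scale range [%g, %g]: extrapolating",
      s_city_m, fit$s_range[1], fit$s_range[2]))
  }
  ce <- fit$k * s_city_m^fit$beta
  level <- if (is.null(fit$conf_level)) 0.95 else fit$conf_level
  if (!is.null(fit$loglog) && fit$fit_space == "log-log") {
    ll <- fit$loglog
    x0 <- log(s_city_m)
    mu <- log(fit$k) + fit$beta * x0
    se_mu <- sqrt(ll$sigma2 * (1 / ll$sw + (x0 - ll$xbar)^2 / ll$sxx))
    tcrit <- stats::qt(1 - (1 - level) / 2, df = ll$df)
    ci <- exp(mu + c(-1, 1) * tcrit * se_mu)
  } else {
    g <- c(s_city_m^fit$beta, ce * log(s_city_m))
    se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
    tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
    ci <- ce + c(-1, 1) * tcrit * se
  }
  list(ce_city = ce, ce_ci = unname(ci))
}

#' Invert city-scale cooling efficiency into a canopy-increase goal
#'
#' The percent canopy increase required for a target LST reduction is
#' `utc_goal_pct = delta_t_target / ce_city`. The interval is obtained
#' by inverting the CE interval endpoint-wise — exact for this monotone
#' transform — with the order flipped because goal and CE are inversely
#' related: `[delta_t / ce_upper, delta_t / ce_lower]`.
#'
#' @param ce_city City-scale CE (deg C per %UTC), > 0.
#' @param ce_ci Optional length-2 CE interval (both endpoints > 0).
#' @param delta_t_target Target LST reduction (deg C), > 0.
#' @param s_city_m Evaluation size carried through for reporting.
#' @return A `city_prediction` list: `s_city_m`, `ce_city`, `ce_ci`,
#'   `delta_t_target`, `utc_goal_pct`, `utc_goal_ci`.
#' @export
utc_goal <- function(ce_city, ce_ci = NULL, delta_t_target,
                     s_city_m = NA_real_) {
  if (!is.numeric(ce_city) || length(ce_city) != 1L || ce_city <= 0) {
    stop_config("`ce_city` must be a single positive number",
                field = "ce_city")
  }
  if (!is.numeric(delta_t_target) || length(delta_t_target) != 1L ||
      delta_t_target <= 0) {
    stop_config("`delta_t_target` must be a single positive number",
                field = "delta_t_target")
  }
  goal_ci <- NULL
  if (!is.null(ce_ci)) {
    if (length(ce_ci) != 2L || any(ce_ci <= 0)) {
      stop_config("`ce_ci` must be two positive endpoints",
                  field = "ce_ci")
    }
    ce_ci <- sort(ce_ci)
    goal_ci <- c(delta_t_target / ce_ci[2], delta_t_target / ce_ci[1])
  }
  structure(
    list(s_city_m = s_city_m, ce_city = ce_city, ce_ci = ce_ci,
         delta_t_target = delta_t_target,
         utc_goal_pct = delta_t_target / ce_city,
         utc_goal_ci = goal_ci),
    class = "city_prediction")
}

#' @export
print.city_prediction <- function(x, ...) {
  cat(sprintf("<city_prediction> at S = %g m\n", x$s_city_m))
  cat(sprintf("  CE(city)      = %.4g degC/%%UTC%s\n", x$ce_city,
              if (!is.null(x$ce_ci)) sprintf("  [%.4g, %.4g]",
                                             x$ce_ci[1], x$ce_ci[2]) else ""))
  cat(sprintf("  target dT     = %.3g degC\n", x$delta_t_target))
  cat(sprintf("  UTC goal      = %.4g %%%s\n", x$utc_goal_pct,
              if (!is.null(x$utc_goal_ci)) sprintf("  [%.4g, %.4g]",
                                                   x$utc_goal_ci[1],
                                                   x$utc_goal_ci[2]) else ""))
  invisible(x)
}
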
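#' Fit the power-law scaling of cooling efficiency with unit size
#'
#' Fits `CE = k * S^beta` to per-scale CE estimates. The default fit
#' space is log-log: OLS of `ln(ce)` on `ln(S)`, so `beta` is the slope
#' and `k = exp(intercept)`, with closed-form 95% confidence intervals
#' from the OLS covariance (the interval for `k` by exponentiating the
#' intercept bounds). A direct nonlinear least-squares fit of
#' `ce = k * S^beta` (initialized from the log-log solution, asymptotic
#' intervals) is available via `fit_space = "direct"`.
#'
#' Non-positive CE values cannot enter the log-log fit and are dropped
#' with a warning; if more than half would be dropped the direct space is
#' used instead. Points are unweighted by default; `weights = "inv_se2"`
#' weights each scale by `1 / se_slope^2`.
#'
#' @param estimates `data.frame` of per-scale CE estimates (columns
#'   `scale_m`, `ce`, optionally `se_slope`), >= 3 rows.
#' @param fit_space `"log-log"` (default) or `"direct"`.
#' @param weights `"none"` (default) or `"inv_se2"`.
#' @param s_unit Unit in which S enters the fit: `"m"` (default) or
#'   `"px"` (requires `base_pixel_m`). `beta` is invariant to this
#'   choice; `k` rescales by `base_pixel_m^beta`.
#' @param base_pixel_m Base pixel size, needed only for `s_unit = "px"`.
#' @param conf_level Confidence level for the parameter intervals.
#' @return An object of class `scaling_fit`: `model_form = "power"`,
#'   `k`, `beta`, `k_ci`, `beta_ci`, `fit_space`, `r2_fit` (fit-space
#'   R^2), `r2_direct` (R^2 of the implied curve on the CE scale),
#'   `p_fit` (significance of the scale term), `n_scales`, `s_unit`,
#'   plus internal summaries used for mean-response prediction bands.
#' @export
fit_power_law <- function(estimates, fit_space = c("log-log", "direct"),
                          weights = c("none", "inv_se2"), s_unit = "m",
                          base_pixel_m = NULL, conf_level = 0.95) {
  fit_space <- match.arg(fit_space)
  weights <- match.arg(weights)
  est <- as.data.frame(estimates)
  if (nrow(est) < 3L) {
    stop_compute(sprintf("power-law fit needs >= 3 scales, got %d",
                         nrow(est)), class = "canopycooler_fit_error")
  }
  s <- scale_values(est, s_unit, base_pixel_m)
  ce <- est$ce
  w <- fit_weights(est, weights)

  if (all(ce <= 0)) {
    stop_compute("all CE values are non-positive; power law cannot be fit",
                 class = "canopycooler_fit_error")
  }
  pos <- ce > 0
  if (fit_space == "log-log" && any(!pos)) {
    if (sum(!pos) > nrow(est) / 2) {
      warning(paste("more than half of the CE values are non-positive;",
                    "falling back to the direct fit space"))
      fit_space <- "direct"
    } else {
      warning(sprintf("dropping %d non-positive CE value(s) from the %s",
                      sum(!pos), "log-log fit"))
    }
  }

  # log-log solution doubles as the initializer for the direct fit
  ll <- loglog_fit(s[pos], ce[pos], w[pos], conf_level)

  if (fit_space == "log-log") {
    out <- ll
  } else {
    df_nls <- data.frame(s = s, ce = ce, w = w)
    nfit <- stats::nls(ce ~ k * s^beta, data = df_nls,
                       start = list(k = ll$k, beta = ll$beta),
                       weights = w,
                       control = stats::nls.control(maxiter = 200))
    cf <- summary(nfit)$coefficients
    tcrit <- stats::qt(1 - (1 - conf_level) / 2,
                       df = nrow(df_nls) - 2L)
    out <- list(
      k = cf["k", "Estimate"], beta = cf["beta", "Estimate"],
      k_ci = cf["k", "Estimate"] + c(-1, 1) * tcrit * cf["k", "Std. Error"],
      beta_ci = cf["beta", "Estimate"] +
        c(-1, 1) * tcrit * cf["beta", "Std. Error"],
      r2_fit = 1 - sum(stats::resid(nfit)^2) / sum((ce - mean(ce))^2),
      p_fit = cf["beta", "Pr(>|t|)"],
      vcov = stats::vcov(nfit), df = nrow(df_nls) - 2L
    )
  }

  out$model_form <- "power"
  out$fit_space <- fit_space
  out$quad_coeffs <- NULL
  out$n_scales <- nrow(est)
  out$s_unit <- s_unit
  out$s_range <- range(s)
  out$conf_level <- conf_level
  out$r2_direct <- 1 - sum((ce - out$k * s^out$beta)^2) /
    sum((ce - mean(ce))^2)
  structure(out, class = "scaling_fit")
}

#' Fit the quadratic fallback model of CE versus unit size
#'
#' OLS of `ce` on `(1, S, S^2)`, the fallback form used when the power
#' law is not significant (typical of extreme-heat days where CE rises
#' then saturates or declines). `p_fit` is the joint F-test of the two
#' scale terms against the intercept-only model.
#'
#' @inheritParams fit_power_law
#' @return A `scaling_fit` with `model_form = "quadratic"`,
#'   `quad_coeffs = c(c0, c1, c2)`, `r2_fit` (direct-space R^2), `p_fit`,
#'   `n_scales`, `s_unit`, `s_range`.
#' @export
fit_quadratic <- function(estimates, s_unit = "m", base_pixel_m = NULL) {
  est <- as.data.frame(estimates)
  if (nrow(est) < 4L) {
    stop_compute(sprintf("quadratic fit needs >= 4 scales, got %d",
                         nrow(est)), class = "canopycooler_fit_error")
  }
  s <- scale_values(est, s_unit, base_pixel_m)
  dat <- data.frame(s = s, ce = est$ce)
  fit <- stats::lm(ce ~ s + I(s^2), data = dat)
  if (any(!is.finite(stats::coef(fit)))) {
    stop_compute("singular design in quadratic fit",
                 class = "canopycooler_fit_error")
  }
  p_joint <- stats::anova(stats::lm(ce ~ 1, data = dat), fit)$`Pr(>F)`[2]
  structure(
    list(model_form = "quadratic", k = NA_real_, beta = NA_real_,
         k_ci = c(NA_real_, NA_real_), beta_ci = c(NA_real_, NA_real_),
         quad_coeffs = unname(stats::coef(fit)),
         quad_vcov = stats::vcov(fit),
         fit_space = "direct", r2_fit = summary(fit)$r.squared,
         r2_direct = summary(fit)$r.squared,
         p_fit = p_joint, n_scales = nrow(est), s_unit = s_unit,
         s_range = range(s)),
    class = "scaling_fit")
}

#' Select between the power-law and quadratic forms
#'
#' The power law is retained when its scale term is significant
#' (`p_fit <= alpha`, default 0.01); otherwise the quadratic fallback is
#' returned. Both fits' diagnostics are attached as `$alternative` and a
#' message records the choice with both direct-space R^2 values, since
#' on extreme days the quadratic can fit better than the power law.
#'
#' @inheritParams fit_power_law
#' @param alpha Significance threshold for keeping the power form.
#' @param quiet Suppress the selection message.
#' @return The selected `scaling_fit`, with the rejected fit in
#'   `$alternative`.
#' @export
select_model <- function(estimates, alpha = 0.01,
                         fit_space = c("log-log", "direct"),
                         weights = c("none", "inv_se2"), s_unit = "m",
                         base_pixel_m = NULL, quiet = FALSE) {
  pw <- fit_power_law(estimates, fit_space = fit_space, weights = weights,
                      s_unit = s_unit, base_pixel_m = base_pixel_m)
  qd <- tryCatch(
    fit_quadratic(estimates, s_unit = s_unit, base_pixel_m = base_pixel_m),
    canopycooler_fit_error = function(e) NULL)
  use_power <- is.finite(pw$p_fit) && pw$p_fit <= alpha
  if (!use_power && is.null(qd)) {
    warning("power fit insignificant but quadratic unavailable; returning power")
    use_power <- TRUE
  }
  chosen <- if (use_power) pw else qd
  chosen$alternative <- if (use_power) qd else pw
  if (!quiet) {
    message(sprintf(
      "model selection: %s (power p=%.3g, R2=%.3f%s; alpha=%.3g)",
      chosen$model_form, pw$p_fit, pw$r2_direct,
      if (!is.null(qd)) sprintf("; quadratic p=%.3g, R2=%.3f",
                                qd$p_fit, qd$r2_fit) else "",
      alpha))
  }
  chosen
}

#' Pool per-date CE estimates into a single power-law fit
#'
#' Fits one power law to the pooled `(ln S, ln CE)` points across dates
#' — the statistically simplest pooled estimator — and also returns the
#' per-date fits so the across-date dispersion of `(k, beta)` can be
#' reported alongside.
#'
#' @param per_date_estimates List (length >= 2) of per-scale CE estimate
#'   `data.frame`s, one per date.
#' @inheritParams fit_power_law
#' @return A `scaling_fit` for the pooled points with elements
#'   `per_date` (list of per-date `scaling_fit`s) and `n_dates`.
#' @export
pool_fits <- function(per_date_estimates,
                      fit_space = c("log-log", "direct"),
                      weights = c("none", "inv_se2"), s_unit = "m",
                      base_pixel_m = NULL) {
  if (length(per_date_estimates) < 2L) {
    stop_compute("pooling needs >= 2 dates",
                 class = "canopycooler_fit_error")
  }
  pooled_tab <- do.call(rbind, lapply(per_date_estimates, as.data.frame))
  pooled <- fit_power_law(pooled_tab, fit_space = fit_space,
                          weights = weights, s_unit = s_unit,
                          base_pixel_m = base_pixel_m)
  pooled$per_date <- lapply(per_date_estimates, fit_power_law,
                            fit_space = fit_space, weights = weights,
                            s_unit = s_unit, base_pixel_m = base_pixel_m)
  pooled$n_dates <- length(per_date_estimates)
  pooled
}

#' @export
print.scaling_fit <- function(x, ...) {
  if (x$model_form == "power") {
    cat(sprintf(
      "<scaling_fit> CE = k * S^beta (%s space, S in %s)\n", x$fit_space,
      x$s_unit))
    cat(sprintf("  k    = %.4g  [%.4g, %.4g]\n", x$k, x$k_ci[1], x$k_ci[2]))
    cat(sprintf("  beta = %.4g  [%.4g, %.4g]\n", x$beta, x$beta_ci[1],
                x$beta_ci[2]))
  } else {
    cat(sprintf(
      "<scaling_fit> CE = c0 + c1*S + c2*S^2 (S in %s)\n  c = (%s)\n",
      x$s_unit, paste(signif(x$quad_coeffs, 4), collapse = ", ")))
  }
  cat(sprintf("  R2 = %.4f (fit space), p = %.3g, n_scales = %d\n",
              x$r2_fit, x$p_fit, x$n_scales))
  invisible(x)
}

#' Serialize a scaling fit to JSON
#'
#' @param fit A `scaling_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaling_fit <- function(fit, path) {
  out <- list(
    model_form = fit$model_form, k = fit$k, beta = fit$beta,
    k_ci = fit$k_ci, beta_ci = fit$beta_ci,
    quad_coeffs = fit$quad_coeffs, fit_space = fit$fit_space,
    r2_fit = fit$r2_fit, r2_direct = fit$r2_direct, p_fit = fit$p_fit,
    n_scales = fit$n_scales, s_unit = fit$s_unit, s_range = fit$s_range,
    loglog = fit$loglog
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Sample the fitted CE curve for plotting
#'
#' @param fit A `scaling_fit`.
#' @param n Number of points across the fitted S range.
#' @return `data.frame` with `s`, `ce_fit`.
#' @export
fitted_curve <- function(fit, n = 200) {
  s <- seq(fit$s_range[1], fit$s_range[2], length.out = n)
  ce <- if (fit$model_form == "power") fit$k * s^fit$beta else
    fit$quad_coeffs[1] + fit$quad_coeffs[2] * s + fit$quad_coeffs[3] * s^2
  data.frame(s = s, ce_fit = ce)
}

# ---- internals --------------------------------------------------------

scale_values <- function(est, s_unit, base_pixel_m) {
  if (identical(s_unit, "m")) return(est$scale_m)
  if (identical(s_unit, "px")) {
    if (is.null(base_pixel_m)) {
      stop_config("`base_pixel_m` is required when s_unit = \"px\"",
                  field = "base_pixel_m")
    }
    return(est$scale_m / base_pixel_m)
  }
  stop_config("`s_unit` must be \"m\" or \"px\"", field = "s_unit")
}

fit_weights <- function(est, weights) {
  if (weights == "none") return(rep(1, nrow(est)))
  if (is.null(est$se_slope) || any(!is.finite(est$se_slope)) ||
      any(est$se_slope <= 0)) {
    stop_config("inv_se2 weighting needs finite positive `se_slope`",
                field = "weights")
  }
  1 / est$se_slope^2
}

# Weighted OLS of ln(ce) on ln(s); returns parameters plus the summary
# statistics needed for closed-form mean-response bands at new S.
loglog_fit <- function(s, ce, w, conf_level) {
  x <- log(s); y <- log(ce)
  fit <- stats::lm(y ~ x, weights = w)
  if (any(!is.finite(stats::coef(fit)))) {
    stop_compute("singular design in log-log fit (constant S?)",
                 class = "canopycooler_fit_error")
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  sxx <- sum(w * (x - xbar)^2)
  df <- length(x) - 2L
  sigma2 <- sum(w * stats::resid(fit)^2) / df
  list(
    k = exp(cf["(Intercept)", "Estimate"]),
    beta = cf["x", "Estimate"],
    k_ci = unname(exp(ci["(Intercept)", ])),
    beta_ci = unname(ci["x", ]),
    r2_fit = summary(fit)$r.squared,
    p_fit = if (df > 0) cf["x", "Pr(>|t|)"] else NA_real_,
    loglog = list(xbar = xbar, sxx = sxx, sw = sw, sigma2 = sigma2,
                  df = df)
  )
}
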
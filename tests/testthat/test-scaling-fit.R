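ce_points <- function(s, ce, se = NULL) {
  data.frame(scale_m = s, ce = ce,
             se_slope = if (is.null(se)) rep(1, length(s)) else se)
}

study_scales <- seq(120, 2760, by = 240)

test_that("exact power-law points are recovered to numerical precision", {
  est <- ce_points(study_scales, 0.057 * study_scales^0.165)
  fit <- suppressWarnings(fit_power_law(est))
  expect_equal(fit$k, 0.057, tolerance = 1e-10)
  expect_equal(fit$beta, 0.165, tolerance = 1e-10)
  expect_identical(fit$model_form, "power")
  expect_equal(fit$r2_fit, 1, tolerance = 1e-10)
  # intervals contain the point estimates
  expect_true(fit$k_ci[1] <= fit$k && fit$k <= fit$k_ci[2])
  expect_true(fit$beta_ci[1] <= fit$beta && fit$beta <= fit$beta_ci[2])
})

test_that("constant CE across scales fits as beta = 0", {
  fit <- suppressWarnings(fit_power_law(ce_points(study_scales, 0.2)))
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$k, 0.2, tolerance = 1e-12)
})

test_that("direct and log-log spaces agree on clean data", {
  set.seed(44)
  ce <- 0.06 * study_scales^0.15 * exp(rnorm(12, 0, 0.01))
  ll <- fit_power_law(ce_points(study_scales, ce), fit_space = "log-log")
  dr <- fit_power_law(ce_points(study_scales, ce), fit_space = "direct")
  expect_equal(dr$beta, ll$beta, tolerance = 0.02)
  expect_equal(dr$k, ll$k, tolerance = 0.05)
  expect_identical(dr$fit_space, "direct")
})

test_that("non-positive CE values are dropped or trigger the direct space", {
  s <- study_scales
  ce <- 0.057 * s^0.165
  one_bad <- ce; one_bad[3] <- 0
  w <- capture_warnings(fit <- fit_power_law(ce_points(s, one_bad)))
  expect_match(w, "non-positive", all = FALSE)
  expect_equal(fit$beta, 0.165, tolerance = 1e-6)
  expect_error(
    suppressWarnings(fit_power_law(ce_points(s, rep(-1, 12)))),
    class = "canopycooler_fit_error")
})

test_that("quadratic fallback recovers coefficients and nests the line", {
  s <- study_scales
  exact <- 0.02 + 3e-4 * s - 6e-8 * s^2
  fit <- suppressWarnings(fit_quadratic(ce_points(s, exact)))
  expect_equal(fit$quad_coeffs, c(0.02, 3e-4, -6e-8), tolerance = 1e-10)
  expect_identical(fit$model_form, "quadratic")
  expect_equal(fit$r2_fit, 1, tolerance = 1e-10)

  # on truly linear points the curvature term's CI covers zero
  set.seed(9)
  lin <- 0.1 + 2e-4 * s + rnorm(12, 0, 0.005)
  fit_l <- fit_quadratic(ce_points(s, lin))
  se_c2 <- sqrt(diag(fit_l$quad_vcov))[3]
  tcrit <- qt(0.975, df = 12 - 3)
  expect_true(abs(fit_l$quad_coeffs[3]) <= tcrit * se_c2)
})

test_that("concave extreme-day points favour the quadratic form", {
  s <- study_scales
  set.seed(17)
  ce <- 0.05 + 3e-4 * s - 8e-8 * s^2 + rnorm(12, 0, 0.004)
  pw <- fit_power_law(ce_points(s, ce))
  qd <- fit_quadratic(ce_points(s, ce))
  expect_gt(qd$r2_fit, pw$r2_direct)
})

test_that("model selection follows the significance rule", {
  s <- study_scales
  set.seed(101)
  clean <- ce_points(s, 0.057 * s^0.165 * exp(rnorm(12, 0, 0.02)))
  sel <- select_model(clean, quiet = TRUE)
  expect_identical(sel$model_form, "power")
  expect_identical(sel$alternative$model_form, "quadratic")

  # flat, noisy, few scales: power p > 0.01 and the fallback kicks in
  set.seed(23)
  flat <- ce_points(c(120, 360, 600, 840), 0.2 * exp(rnorm(4, 0, 0.3)))
  sel_f <- select_model(flat, quiet = TRUE)
  expect_gt(fit_power_law(flat)$p_fit, 0.01)
  expect_identical(sel_f$model_form, "quadratic")
})

test_that("pooling fits the combined points and brackets per-date fits", {
  s <- study_scales
  one <- ce_points(s, 0.057 * s^0.165)
  pooled_same <- suppressWarnings(pool_fits(list(one, one)))
  single <- suppressWarnings(fit_power_law(one))
  expect_equal(pooled_same$beta, single$beta, tolerance = 1e-10)
  expect_equal(pooled_same$k, single$k, tolerance = 1e-10)

  lo <- ce_points(s, 0.08 * s^0.06)
  hi <- ce_points(s, 0.08 * s^0.10)
  pooled <- suppressWarnings(pool_fits(list(lo, hi)))
  expect_gt(pooled$beta, 0.06)
  expect_lt(pooled$beta, 0.10)

  # 10 simulated dates around the study parameters: the pooled fit lies
  # within the spread of the per-date fits
  set.seed(77)
  dates <- lapply(1:10, function(i) {
    ce_points(s, (0.057 * exp(rnorm(1, 0, 0.1))) *
                s^(0.165 + rnorm(1, 0, 0.02)) * exp(rnorm(12, 0, 0.02)))
  })
  pf <- pool_fits(dates)
  per_beta <- vapply(pf$per_date, function(f) f$beta, 0)
  per_k <- vapply(pf$per_date, function(f) f$k, 0)
  expect_gte(pf$beta, min(per_beta)); expect_lte(pf$beta, max(per_beta))
  expect_gte(pf$k, min(per_k)); expect_lte(pf$k, max(per_k))
  expect_identical(pf$n_dates, 10L)
  expect_error(pool_fits(list(one)), class = "canopycooler_fit_error")
})

test_that("the fit is equivariant to the unit of S and the scale of CE", {
  set.seed(55)
  ce <- 0.057 * study_scales^0.165 * exp(rnorm(12, 0, 0.05))
  est <- ce_points(study_scales, ce)
  fit_m <- fit_power_law(est, s_unit = "m")
  fit_px <- fit_power_law(est, s_unit = "px", base_pixel_m = 120)
  expect_equal(fit_px$beta, fit_m$beta, tolerance = 1e-10)
  expect_equal(fit_px$k, fit_m$k * 120^fit_m$beta, tolerance = 1e-10)

  # multiplying all CE by a constant is absorbed by k; beta unchanged
  fit_2 <- fit_power_law(ce_points(study_scales, 2 * ce))
  expect_equal(fit_2$beta, fit_m$beta, tolerance = 1e-12)
  expect_equal(fit_2$k, 2 * fit_m$k, tolerance = 1e-10)
  expect_equal(fit_2$r2_fit, fit_m$r2_fit, tolerance = 1e-12)
})

test_that("inverse-variance weighting and serialization work", {
  set.seed(66)
  ce <- 0.057 * study_scales^0.165 * exp(rnorm(12, 0, 0.05))
  est <- ce_points(study_scales, ce, se = seq(0.001, 0.012, length.out = 12))
  fw <- fit_power_law(est, weights = "inv_se2")
  fu <- fit_power_law(est, weights = "none")
  expect_false(identical(fw$beta, fu$beta))
  path <- withr::local_tempfile(fileext = ".json")
  write_scaling_fit(fw, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$beta, fw$beta, tolerance = 1e-12)
  expect_identical(back$model_form, "power")
})

test_that("simulated replicates recover the study parameters on average", {
  betas <- vapply(1:30, function(seed) {
    cfg <- tabular_sim_config(k = 0.10, beta = 0.102, noise_sd = 0.5,
                              n_per_scale = 300, seed = seed)
    fit_power_law(estimate_all(simulate_unit_tables(cfg)))$beta
  }, 0)
  expect_lt(abs(mean(betas) - 0.102), 0.01)
})
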
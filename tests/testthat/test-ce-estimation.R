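unit_table <- function(ptree, lst, scale_m = 120) {
  tab <- data.frame(scale_m = scale_m, unit_id = seq_along(ptree),
                    ptree_pct = ptree, lst_mean_c = lst,
                    n_valid_px = 1L, valid_fraction = 1)
  attr(tab, "scale_m") <- scale_m
  tab
}

test_that("CE is the absolute slope, with sign and fit diagnostics", {
  p <- seq(0, 100, by = 5)
  est <- suppressWarnings(estimate_ce(unit_table(p, 40 - 0.1 * p)))
  expect_equal(est$ce, 0.1, tolerance = 1e-12)
  expect_identical(est$slope_sign, "negative")
  expect_equal(est$r2, 1, tolerance = 1e-12)
  expect_equal(est$intercept_c, 40, tolerance = 1e-12)

  # a warming slope is retained as |slope| but flagged
  w <- capture_warnings(est_w <- estimate_ce(unit_table(p, 20 + 0.1 * p)))
  expect_match(w, "positive", all = FALSE)
  expect_equal(est_w$ce, 0.1, tolerance = 1e-12)
  expect_identical(est_w$slope_sign, "positive")
})

test_that("OLS output matches the normal-equations oracle", {
  set.seed(31)
  p <- runif(500, 0, 100)
  lst <- 38 - 0.25 * p + rnorm(500, 0, 0.5)
  est <- estimate_ce(unit_table(p, lst))
  o <- ols_oracle(p, lst)
  expect_equal(est$ce, abs(o$slope), tolerance = 1e-9)
  expect_equal(est$intercept_c, o$intercept, tolerance = 1e-9)
  expect_equal(est$se_slope, o$se_slope, tolerance = 1e-9)
  expect_equal(est$r2, o$r2, tolerance = 1e-9)
  expect_equal(est$p_slope, o$p_slope, tolerance = 1e-9)
  # R^2 equals the squared Pearson correlation
  expect_equal(est$r2, cor(p, lst)^2, tolerance = 1e-10)
  # robust-SE option changes only the uncertainty, not the estimate
  est_r <- estimate_ce(unit_table(p, lst), robust_se = TRUE)
  expect_equal(est_r$ce, est$ce)
  expect_false(identical(est_r$se_slope, est$se_slope))
})

test_that("noiseless simulation recovers the scaling law at every scale", {
  cfg <- tabular_sim_config(k = 0.057, beta = 0.165, noise_sd = 0,
                            n_per_scale = 100, seed = 5)
  est <- suppressWarnings(estimate_all(simulate_unit_tables(cfg)))
  expect_equal(est$ce, 0.057 * est$scale_m^0.165, tolerance = 1e-8)
  expect_true(all(est$slope_sign == "negative"))
})

test_that("degenerate designs are rejected or skipped with warnings", {
  p <- seq(0, 100, by = 10)
  expect_error(estimate_ce(unit_table(p[1:2], c(30, 31))),
               class = "canopycooler_estimation_error")
  expect_error(estimate_ce(unit_table(rep(50, 10), rnorm(10, 30))),
               "zero Ptree variance")

  # one degenerate scale among 12 -> 11 estimates and a warning
  tabs <- simulate_unit_tables(tabular_sim_config(n_per_scale = 50,
                                                  seed = 6))
  tabs[[4]]$ptree_pct <- 50
  expect_warning(est <- estimate_all(tabs), "skipping scale")
  expect_identical(nrow(est), 11L)

  # fewer than 3 usable scales -> pipeline error
  expect_error(estimate_all(tabs[1:2]),
               class = "canopycooler_pipeline_error")
})

test_that("CE is offset-invariant and scales with LST units", {
  set.seed(12)
  p <- runif(200, 10, 90)
  lst <- 35 - 0.12 * p + rnorm(200, 0, 0.3)
  base <- estimate_ce(unit_table(p, lst))
  shifted <- estimate_ce(unit_table(p, lst + 7.3))
  scaled <- estimate_ce(unit_table(p, lst * 1.8))
  expect_equal(shifted$ce, base$ce, tolerance = 1e-12)
  expect_equal(shifted$r2, base$r2, tolerance = 1e-12)
  expect_equal(scaled$ce, 1.8 * base$ce, tolerance = 1e-12)
})

test_that("per-scale R^2 tends to increase with unit size", {
  # with fixed LST noise and a growing true slope, the explained share
  # of variance must grow with S; check the rank correlation on average
  rhos <- vapply(1:10, function(seed) {
    cfg <- tabular_sim_config(k = 0.057, beta = 0.165, noise_sd = 1,
                              n_per_scale = 200, seed = seed)
    est <- estimate_all(simulate_unit_tables(cfg))
    cor(est$scale_m, est$r2, method = "spearman")
  }, 0)
  expect_gte(mean(rhos), 0)
})
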
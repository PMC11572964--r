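#' Seeded parameter-recovery experiment for the CE scaling law
#'
#' Repeatedly (a) draws per-scale unit samples from the tabular
#' generator with a known `(k, beta)` truth, (b) estimates CE at every
#' scale by OLS, and (c) fits the power law, returning the per-replicate
#' fitted parameters. This is the calibration experiment showing that
#' the estimation-plus-fitting stack recovers the printed study
#' parameters from data that embed them.
#'
#' @param k,beta Truth parameters of the generator.
#' @param n_reps Number of replicates.
#' @param scales,n_per_scale,noise_sd Generator settings (defaults: the
#'   12 study scales 120-2760 m, 1000 units per scale, 0.5 deg C noise).
#' @param seeds Integer vector of per-replicate seeds (length `n_reps`);
#'   defaults to `1:n_reps`.
#' @param fit_space Passed to [fit_power_law()].
#' @return `data.frame` with one row per replicate: `seed`, `k_hat`,
#'   `beta_hat`, plus attributes `mean_k`, `mean_beta`.
#' @export
recover_scaling_params <- function(k, beta, n_reps = 200,
                                   scales = seq(120, 2760, by = 240),
                                   n_per_scale = 1000, noise_sd = 0.5,
                                   seeds = seq_len(n_reps),
                                   fit_space = "log-log") {
  stopifnot(length(seeds) == n_reps)
  rows <- lapply(seeds, function(s) {
    cfg <- tabular_sim_config(k = k, beta = beta, scales = scales,
                              n_per_scale = n_per_scale,
                              noise_sd = noise_sd, seed = s)
    fit <- fit_power_law(estimate_all(simulate_unit_tables(cfg)),
                         fit_space = fit_space)
    data.frame(seed = s, k_hat = fit$k, beta_hat = fit$beta)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_k") <- mean(out$k_hat)
  attr(out, "mean_beta") <- mean(out$beta_hat)
  attr(out, "truth") <- c(k = k, beta = beta)
  out
}
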
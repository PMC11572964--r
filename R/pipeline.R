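#' Build a validated pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the input source (paths
#' to rasters, a raster simulation config, or a tabular simulation
#' config — single- or multi-date), the scale ladder, aggregation and
#' fitting options, and optional prediction and weather stages. All
#' randomness flows from the single `seed`: per-date sub-seeds are drawn
#' from it so each date is independently reproducible.
#'
#' @param input Either a list of per-date inputs or a single input; each
#'   input is a `tabular_sim_config`, a `raster_sim_config`, or a list
#'   `list(lst_path =, canopy_path =, boundary_path = NULL)`.
#' @param base_pixel_m,w_max Ladder parameters (see [make_ladder()]).
#' @param min_valid_fraction Passed to [aggregate_units()].
#' @param fit_space,weights,alpha Fitting options (see [select_model()]).
#' @param s_city_m Evaluation size for the prediction stage; defaults to
#'   the largest ladder size.
#' @param delta_t_target Optional target LST reduction (deg C); when set,
#'   the prediction stage runs and a canopy goal is reported.
#' @param weather Optional `data.frame` of per-date weather records (see
#'   [correlate_exponents()]); used only with >= 3 dates.
#' @param out_dir Output directory for all artefacts.
#' @param seed Master seed.
#' @return A validated `run_config`.
#' @export
run_config <- function(input, base_pixel_m = 120, w_max = 23,
                       min_valid_fraction = 0.5,
                       fit_space = "log-log", weights = "none",
                       alpha = 0.01, s_city_m = NULL,
                       delta_t_target = NULL, weather = NULL,
                       out_dir = tempfile("canopycooler_run_"),
                       seed = 1L) {
  # validate the ladder up front so bad configs fail before any compute
  ladder <- make_ladder(base_pixel_m, w_max)
  if (is.null(s_city_m)) s_city_m <- max(ladder$sizes_m)

  is_input <- function(x) {
    inherits(x, "tabular_sim_config") || inherits(x, "raster_sim_config") ||
      (is.list(x) && !is.null(x$lst_path) && !is.null(x$canopy_path))
  }
  inputs <- if (is_input(input)) list(input) else input
  if (!all(vapply(inputs, is_input, logical(1)))) {
    stop_config(paste("`input` must be (a list of) simulation configs or",
                      "lst/canopy path lists"), field = "input")
  }
  structure(
    list(inputs = inputs, base_pixel_m = base_pixel_m, w_max = w_max,
         min_valid_fraction = min_valid_fraction, fit_space = fit_space,
         weights = weights, alpha = alpha, s_city_m = s_city_m,
         delta_t_target = delta_t_target, weather = weather,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full cooling-efficiency scaling pipeline
#'
#' Executes aggregate -> estimate -> fit -> (optional) predict ->
#' (optional, multi-date) weather, writing every intermediate table
#' beneath `config$out_dir` and returning a manifest that records the
#' package version, seed, config hash, and per-stage row counts. With a
#' single date the fit stage applies the power/quadratic model-selection
#' rule; with several dates the per-date estimates are pooled into one
#' power fit and per-date fits are kept for dispersion reporting.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`; notable elements: `fit` (the selected or pooled
#'   `scaling_fit`), `prediction`, `weather`, `estimates`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_path)
  say <- function(...) if (!quiet) message(sprintf(...))

  set.seed(config$seed)
  date_seeds <- sample.int(.Machine$integer.max, length(config$inputs))
  ladder <- make_ladder(config$base_pixel_m, config$w_max)

  estimates <- vector("list", length(config$inputs))
  counts <- list()
  for (i in seq_along(config$inputs)) {
    inp <- config$inputs[[i]]
    tag <- sprintf("date%02d", i)
    tables <- with_stage(tag, "aggregate", {
      date_tables(inp, ladder, config, date_seeds[i])
    })
    write_unit_tables(tables, file.path(config$out_dir, tag))
    est <- with_stage(tag, "estimate", estimate_all(tables))
    utils::write.csv(est, file.path(config$out_dir, tag, "estimates.csv"),
                     row.names = FALSE)
    estimates[[i]] <- est
    counts[[tag]] <- list(n_scales = nrow(est),
                          n_units = sum(vapply(tables, nrow, 0L)))
    say("[%s] %d scales estimated from %d units", tag, nrow(est),
        counts[[tag]]$n_units)
  }

  fit <- with_stage("all", "fit", {
    if (length(estimates) == 1L) {
      select_model(estimates[[1]], alpha = config$alpha,
                   fit_space = config$fit_space,
                   weights = config$weights, quiet = quiet)
    } else {
      pool_fits(estimates, fit_space = config$fit_space,
                weights = config$weights)
    }
  })
  write_scaling_fit(fit, file.path(config$out_dir, "fit.json"))
  utils::write.csv(fitted_curve(fit),
                   file.path(config$out_dir, "fit_curve.csv"),
                   row.names = FALSE)
  if (!is.null(fit$per_date)) {
    for (i in seq_along(fit$per_date)) {
      write_scaling_fit(fit$per_date[[i]],
                        file.path(config$out_dir,
                                  sprintf("date%02d", i), "fit.json"))
    }
  }
  say("[all] %s fit: k=%.4g beta=%.4g (R2=%.3f)", fit$model_form,
      fit$k, fit$beta, fit$r2_fit)

  prediction <- NULL
  if (!is.null(config$delta_t_target) && fit$model_form == "power") {
    prediction <- with_stage("all", "predict", {
      pr <- predict_ce(fit, config$s_city_m)
      utc_goal(pr$ce_city, pr$ce_ci, config$delta_t_target,
               s_city_m = config$s_city_m)
    })
    jsonlite::write_json(unclass(prediction),
                         file.path(config$out_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("[all] CE(city) = %.4g; UTC goal for %.2g degC = %.4g%%",
        prediction$ce_city, prediction$delta_t_target,
        prediction$utc_goal_pct)
  }

  weather_res <- NULL
  if (!is.null(config$weather) && length(estimates) >= 3L &&
      !is.null(fit$per_date)) {
    betas <- data.frame(
      date_id = config$weather$date_id[seq_along(fit$per_date)],
      beta = vapply(fit$per_date, function(f) f$beta, 0))
    weather_res <- with_stage("all", "weather",
                              correlate_exponents(betas, config$weather))
    utils::write.csv(weather_res,
                     file.path(config$out_dir, "weather.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "canopycooler",
    version = as.character(utils::packageVersion("canopycooler")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = counts,
    fit = list(model_form = fit$model_form, k = fit$k, beta = fit$beta,
               r2_fit = fit$r2_fit, p_fit = fit$p_fit,
               n_scales = fit$n_scales),
    prediction = if (!is.null(prediction)) unclass(prediction),
    weather = if (!is.null(weather_res))
      list(n_dates = weather_res$n_dates[1])
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest$fit_object <- fit
  manifest$estimates <- estimates
  manifest$prediction_object <- prediction
  manifest$weather_result <- weather_res
  invisible(manifest)
}

# ---- internals --------------------------------------------------------

# Resolve one date's input into unit tables at every ladder scale.
date_tables <- function(inp, ladder, config, sub_seed) {
  if (inherits(inp, "tabular_sim_config")) {
    inp$seed <- sub_seed
    return(simulate_unit_tables(inp))
  }
  pair <- if (inherits(inp, "raster_sim_config")) {
    args <- unclass(inp)
    args$seed <- sub_seed
    args$max_unit_px <- max(ladder$widths_px)
    simulate_raster_pair(do.call(raster_sim_config, args))
  } else {
    load_raster_pair(inp$lst_path, inp$canopy_path, inp$boundary_path,
                     quiet = TRUE)
  }
  pair <- coarsen_canopy(pair)
  aggregate_units(pair, ladder,
                  min_valid_fraction = config$min_valid_fraction)
}

# Propagate failures with the stage / date they came from.
with_stage <- function(tag, stage, expr) {
  tryCatch(expr, canopycooler_error = function(e) {
    stop_compute(sprintf("[%s/%s] %s", tag, stage, conditionMessage(e)),
                 class = class(e)[1])
  })
}

serializable_config <- function(config) {
  out <- unclass(config)
  out$inputs <- lapply(out$inputs, function(x) {
    c(list(type = if (inherits(x, "tabular_sim_config")) "tabular_sim"
           else if (inherits(x, "raster_sim_config")) "raster_sim"
           else "files"),
      lapply(unclass(x), function(v) if (is.null(v)) NA else v))
  })
  if (!is.null(out$weather)) out$weather <- as.list(out$weather)
  out
}
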
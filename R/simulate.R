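#' Configuration for the tabular unit-sample generator
#'
#' Describes a truth model in which the cooling efficiency at unit size S
#' is exactly `k * S^beta` (degrees C of LST reduction per percentage
#' point of canopy cover), so that per-scale unit samples drawn from it
#' have a known OLS slope. Used to test slope estimation and power-law
#' fitting end to end.
#'
#' @param k Normalization constant (deg C per %UTC at S = 1 in the chosen
#'   size unit); must be positive.
#' @param beta Scaling exponent (dimensionless).
#' @param scales Strictly increasing positive unit sizes S in metres.
#' @param n_per_scale Units drawn per scale.
#' @param intercept Baseline LST (deg C) at zero canopy cover.
#' @param noise_sd Residual LST standard deviation (deg C), >= 0.
#' @param ptree_range Length-2 percent-cover bounds, 0 <= low < high <= 100.
#' @param ptree_dist `"uniform"` (default, guarantees slope
#'   identifiability at every scale) or `"beta"` (a Beta(2, 2) shape
#'   rescaled onto `ptree_range`).
#' @param intercept_varies If `TRUE`, each scale gets its own intercept
#'   (`intercept` plus a deterministic offset spread over scales); the
#'   per-scale regressions have free intercepts, so the truth model need
#'   not share one.
#' @param seed RNG seed (integer) for reproducible draws.
#' @return A validated `tabular_sim_config` list.
#' @export
tabular_sim_config <- function(k = 0.057, beta = 0.165,
                               scales = seq(120, 2760, by = 240),
                               n_per_scale = 1000, intercept = 40,
                               noise_sd = 0.5, ptree_range = c(0, 100),
                               ptree_dist = c("uniform", "beta"),
                               intercept_varies = FALSE, seed = 1L) {
  ptree_dist <- match.arg(ptree_dist)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop_config("`k` must be a single positive number", field = "k")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop_config("`beta` must be a single finite number", field = "beta")
  }
  if (!is.numeric(scales) || length(scales) < 1L || any(scales <= 0) ||
      is.unsorted(scales, strictly = TRUE)) {
    stop_config("`scales` must be strictly increasing and positive",
                field = "scales")
  }
  if (!is.numeric(n_per_scale) || n_per_scale < 2) {
    stop_config("`n_per_scale` must be at least 2", field = "n_per_scale")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_config("`noise_sd` must be >= 0", field = "noise_sd")
  }
  if (length(ptree_range) != 2L || ptree_range[1] < 0 ||
      ptree_range[2] > 100 || ptree_range[1] >= ptree_range[2]) {
    stop_config("`ptree_range` must satisfy 0 <= low < high <= 100",
                field = "ptree_range")
  }
  structure(
    list(k = k, beta = beta, scales = as.numeric(scales),
         n_per_scale = as.integer(n_per_scale), intercept = intercept,
         noise_sd = noise_sd, ptree_range = as.numeric(ptree_range),
         ptree_dist = ptree_dist, intercept_varies = intercept_varies,
         seed = as.integer(seed)),
    class = "tabular_sim_config"
  )
}

#' Simulate per-scale unit tables with a known CE scaling law
#'
#' For each scale S in the config, draws `n_per_scale` analytical units
#' with percent canopy cover `ptree_pct` on `ptree_range` and
#' `lst_mean_c = intercept - (k * S^beta) * ptree_pct + eps`,
#' `eps ~ N(0, noise_sd^2)`. The per-scale population OLS slope is thus
#' exactly `-(k * S^beta)`, i.e. the cooling efficiency is `k * S^beta`.
#' Deterministic given `config$seed`.
#'
#' @param config A [tabular_sim_config()].
#' @return A list of unit tables (one `data.frame` per scale, ordered as
#'   `config$scales`), each with columns `scale_m`, `unit_id`,
#'   `ptree_pct`, `lst_mean_c`, `n_valid_px`, `valid_fraction` and
#'   attribute `scale_m`.
#' @export
simulate_unit_tables <- function(config) {
  stopifnot(inherits(config, "tabular_sim_config"))
  set.seed(config$seed)
  n <- config$n_per_scale
  lo <- config$ptree_range[1]; hi <- config$ptree_range[2]
  ns <- length(config$scales)
  intercepts <- if (isTRUE(config$intercept_varies)) {
    config$intercept + seq(0, 2, length.out = ns)
  } else rep(config$intercept, ns)

  tabs <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- config$scales[i]
    ptree <- switch(config$ptree_dist,
      uniform = stats::runif(n, lo, hi),
      beta    = lo + (hi - lo) * stats::rbeta(n, 2, 2)
    )
    eps <- if (config$noise_sd > 0) {
      stats::rnorm(n, 0, config$noise_sd)
    } else rep(0, n)
    lst <- intercepts[i] - (config$k * s^config$beta) * ptree + eps
    tab <- data.frame(
      scale_m = s, unit_id = seq_len(n), ptree_pct = ptree,
      lst_mean_c = lst, n_valid_px = 1L, valid_fraction = 1
    )
    attr(tab, "scale_m") <- s
    tabs[[i]] <- tab
  }
  tabs
}

#' Configuration for the synthetic raster-pair generator
#'
#' Describes a canopy field (a thresholded correlated Gaussian random
#' field, mimicking patch structure with a controllable correlation
#' range) and an LST field coupled to it through a local term plus a
#' neighbourhood-smoothed term. The smoothed term is what makes the
#' estimated cooling efficiency grow with unit size: at the base scale
#' the smoothed cover is an imperfect proxy for pixel cover, so the
#' bivariate slope under-counts it, while unit means at scales much
#' larger than the smoothing radius recover the full local-plus-
#' neighbourhood effect. This emulates the patch-size dependence of
#' evapotranspirative cooling without any radiometric modelling.
#'
#' @param n_rows,n_cols Base-grid dimensions in pixels.
#' @param pixel_size Base pixel size in metres.
#' @param canopy_corr_range Spatial correlation range of the canopy field
#'   (m), > 0.
#' @param canopy_cover_target Mean fractional cover in (0, 1).
#' @param baseline_c Baseline LST (deg C) at zero cover.
#' @param local_effect Deg C of cooling per unit local cover, >= 0.
#' @param neighborhood_effect Deg C per unit neighbourhood-smoothed cover,
#'   >= 0.
#' @param neighborhood_range Smoothing radius (m), > 0.
#' @param noise_sd Pixel LST noise sd (deg C), >= 0.
#' @param max_unit_px Optional largest unit width (base px) the raster is
#'   intended to support; dimensions smaller than three times this value
#'   are rejected with advice to enlarge the grid.
#' @param seed RNG seed.
#' @return A validated `raster_sim_config` list.
#' @export
raster_sim_config <- function(n_rows = 120, n_cols = 120, pixel_size = 120,
                              canopy_corr_range = 600,
                              canopy_cover_target = 0.3,
                              baseline_c = 40, local_effect = 5,
                              neighborhood_effect = 5,
                              neighborhood_range = 600,
                              noise_sd = 0.5, max_unit_px = NULL,
                              seed = 1L) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop_config(sprintf("`%s` must be a single positive number", nm),
                  field = nm)
    }
  }
  chk_pos(n_rows, "n_rows"); chk_pos(n_cols, "n_cols")
  chk_pos(pixel_size, "pixel_size")
  chk_pos(canopy_corr_range, "canopy_corr_range")
  chk_pos(neighborhood_range, "neighborhood_range")
  if (canopy_cover_target <= 0 || canopy_cover_target >= 1) {
    stop_config("`canopy_cover_target` must lie in (0, 1)",
                field = "canopy_cover_target")
  }
  if (local_effect < 0 || neighborhood_effect < 0) {
    stop_config("effects must be >= 0",
                field = "local_effect/neighborhood_effect")
  }
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0", field = "noise_sd")
  if (!is.null(max_unit_px) && min(n_rows, n_cols) < 3 * max_unit_px) {
    stop_config(sprintf(
      paste0("grid (%d x %d px) is smaller than 3x the largest requested ",
             "unit (%d px); enlarge the grid so each scale has enough ",
             "units"), n_rows, n_cols, as.integer(max_unit_px)),
      field = "max_unit_px")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = pixel_size, canopy_corr_range = canopy_corr_range,
         canopy_cover_target = canopy_cover_target,
         baseline_c = baseline_c, local_effect = local_effect,
         neighborhood_effect = neighborhood_effect,
         neighborhood_range = neighborhood_range, noise_sd = noise_sd,
         max_unit_px = max_unit_px, seed = as.integer(seed)),
    class = "raster_sim_config"
  )
}

#' Simulate a co-registered LST / canopy raster pair
#'
#' The canopy raster is a correlated Gaussian random field thresholded at
#' the quantile matching the cover target, giving a binary (0/1) cover
#' map at base resolution whose realized mean cover matches the target to
#' within the grid's discretization. The LST raster is
#' `baseline_c - local_effect * cover - neighborhood_effect *
#' smooth(cover, neighborhood_range) + noise`. Both rasters share the
#' geotransform and have no nodata inside the simulated footprint.
#' Deterministic given `config$seed`.
#'
#' @param config A [raster_sim_config()].
#' @return A [raster_pair()] whose canopy is binary at base resolution.
#' @export
simulate_raster_pair <- function(config) {
  stopifnot(inherits(config, "raster_sim_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  px <- config$pixel_size

  field <- gaussian_field(nr, nc, config$canopy_corr_range / px)
  thr <- stats::quantile(field, 1 - config$canopy_cover_target,
                         names = FALSE)
  cover <- (field > thr) + 0

  smoothed <- gaussian_blur(cover, config$neighborhood_range / px)
  noise <- if (config$noise_sd > 0) {
    matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  } else 0
  lst <- config$baseline_c - config$local_effect * cover -
    config$neighborhood_effect * smoothed + noise

  origin <- c(0, nr * px)
  raster_pair(
    lst = raster_grid(lst, pixel_size = px, origin = origin),
    canopy = raster_grid(cover, pixel_size = px, origin = origin)
  )
}

# Stationary Gaussian random field on a torus via FFT convolution of
# white noise with a Gaussian kernel; `range_px` is the kernel sd in
# pixels. Standardized to zero mean / unit sd before thresholding.
gaussian_field <- function(nr, nc, range_px) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- gaussian_blur(white, range_px)
  (f - mean(f)) / stats::sd(f)
}

# Circular (wrap-around) Gaussian smoothing by FFT; kernel is normalized
# to sum 1 so a constant field is preserved.
gaussian_blur <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * sd_px^2))
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
}

#' Write the artefacts of a simulation run to disk
#'
#' Rasters go out as Esri ASCII grids, unit tables as one CSV per scale,
#' and the generating configuration as YAML alongside them.
#'
#' @param x A [raster_pair()] or the list of unit tables from
#'   [simulate_unit_tables()].
#' @param dir Output directory (created if missing).
#' @param config The generating config, archived as `config.yaml`.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(x, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "raster_pair")) {
    write_ascii_grid(x$lst, file.path(dir, "lst.asc"))
    write_ascii_grid(x$canopy, file.path(dir, "canopy.asc"))
  } else {
    for (tab in x) {
      s <- attr(tab, "scale_m")
      utils::write.csv(tab, file.path(dir, sprintf("units_%05d.csv",
                                                   round(s))),
                       row.names = FALSE)
    }
  }
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
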
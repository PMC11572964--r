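#' Build the ladder of analytical-unit sizes
#'
#' Units of analysis are square tiles of w x w base pixels with odd
#' widths 1, 3, 5, ..., `w_max`, so sizes in metres are
#' `widths * base_pixel_m` exactly. With a 120 m base pixel, `w_max = 23`
#' tops out at 2,760 m and `w_max = 37` at 4,440 m; the maximum should be
#' chosen from the size of the study area. Arbitrary (even) widths are
#' available behind `odd_only = FALSE` for sensitivity analysis.
#'
#' @param base_pixel_m Base pixel size in metres, > 0.
#' @param w_max Largest unit width in base pixels; odd and >= 1 unless
#'   `odd_only = FALSE`.
#' @param odd_only Restrict widths to the odd ladder (default).
#' @return An object of class `scale_ladder` with `base_pixel_m`,
#'   `widths_px`, and `sizes_m`.
#' @export
make_ladder <- function(base_pixel_m, w_max, odd_only = TRUE) {
  if (!is.numeric(base_pixel_m) || base_pixel_m <= 0) {
    stop_config("`base_pixel_m` must be positive", field = "base_pixel_m")
  }
  if (!is.numeric(w_max) || length(w_max) != 1L || w_max < 1 ||
      w_max != round(w_max)) {
    stop_config("`w_max` must be a positive integer", field = "w_max")
  }
  if (odd_only && w_max %% 2 == 0) {
    stop_config(sprintf("`w_max` must be odd, got %d", as.integer(w_max)),
                field = "w_max")
  }
  widths <- if (odd_only) seq(1L, as.integer(w_max), by = 2L) else
    seq_len(as.integer(w_max))
  structure(
    list(base_pixel_m = as.numeric(base_pixel_m),
         widths_px = widths,
         sizes_m = widths * as.numeric(base_pixel_m)),
    class = "scale_ladder"
  )
}

#' @export
print.scale_ladder <- function(x, ...) {
  cat(sprintf("<scale_ladder> base %g m; widths %s px (sizes %g..%g m)\n",
              x$base_pixel_m, paste(range(x$widths_px), collapse = ".."),
              min(x$sizes_m), max(x$sizes_m)))
  invisible(x)
}

#' Aggregate a raster pair into per-unit samples at every ladder scale
#'
#' For each width w, the base grid is tiled by w x w tiles anchored at
#' the raster's top-left corner; partial tiles at the right/bottom edges
#' are discarded. Per tile, `ptree_pct` is 100 times the mean fractional
#' cover over valid pixels and `lst_mean_c` the mean LST over valid
#' pixels. A base pixel is valid only when LST and cover are both
#' non-missing and (when a boundary mask is present) inside the boundary.
#' Tiles whose valid fraction falls below `min_valid_fraction` are
#' dropped. Scales at which no tile survives yield an empty table with a
#' warning rather than an error.
#'
#' @param pair A [raster_pair()] with fractional (or base-resolution
#'   binary) cover; run [coarsen_canopy()] first for fine binary maps.
#' @param ladder A [make_ladder()] result.
#' @param min_valid_fraction Minimum fraction of valid pixels a tile must
#'   contain to be kept; default 0.5, the common zonal-statistics
#'   half-support convention.
#' @return A list of unit tables, one per ladder scale (columns
#'   `scale_m`, `unit_id`, `ptree_pct`, `lst_mean_c`, `n_valid_px`,
#'   `valid_fraction`; attribute `scale_m`). Tables where the across-unit
#'   Ptree variance is exactly zero carry attribute `zero_ptree_var`.
#' @export
aggregate_units <- function(pair, ladder, min_valid_fraction = 0.5) {
  stopifnot(inherits(pair, "raster_pair"), inherits(ladder, "scale_ladder"))
  if (pair$ratio != 1L) {
    stop_config(paste("canopy is at finer resolution than LST;",
                      "run coarsen_canopy() first"), field = "pair")
  }
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop_config("`min_valid_fraction` must lie in (0, 1]",
                field = "min_valid_fraction")
  }
  lst <- pair$lst$values
  cover <- pair$canopy$values
  valid <- !is.na(lst) & !is.na(cover)
  if (!is.null(pair$boundary)) {
    valid <- valid & !is.na(pair$boundary$values) &
      pair$boundary$values != 0
  }
  lst[!valid] <- NA_real_
  cover[!valid] <- NA_real_

  lapply(seq_along(ladder$widths_px), function(i) {
    w <- ladder$widths_px[i]
    s <- ladder$sizes_m[i]
    bs_l <- block_stats(lst, w)
    bs_c <- block_stats(cover, w)
    n_valid <- as.vector(t(bs_l$n_valid))      # row-major unit ordering
    vf <- n_valid / (w * w)
    keep <- vf >= min_valid_fraction & n_valid > 0
    tab <- data.frame(
      scale_m = rep(s, sum(keep)),
      unit_id = seq_along(n_valid)[keep],
      ptree_pct = 100 * as.vector(t(bs_c$sum))[keep] / n_valid[keep],
      lst_mean_c = as.vector(t(bs_l$sum))[keep] / n_valid[keep],
      n_valid_px = as.integer(n_valid[keep]),
      valid_fraction = vf[keep]
    )
    attr(tab, "scale_m") <- s
    if (nrow(tab) == 0L) {
      warning(sprintf("no unit at scale %g m meets min_valid_fraction %.2f",
                      s, min_valid_fraction))
    } else if (nrow(tab) >= 2L && stats::var(tab$ptree_pct) == 0) {
      attr(tab, "zero_ptree_var") <- TRUE
      warning(sprintf(
        "units at scale %g m have zero Ptree variance (no slope information)",
        s))
    }
    tab
  })
}

#' Write unit tables and a manifest to a directory
#'
#' One CSV per scale plus a JSON manifest listing the scales and unit
#' counts.
#'
#' @param tables List of unit tables from [aggregate_units()] or
#'   [simulate_unit_tables()].
#' @param dir Output directory (created if missing).
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
write_unit_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scales = list())
  for (tab in tables) {
    s <- attr(tab, "scale_m")
    f <- sprintf("units_%05d.csv", round(s))
    utils::write.csv(tab, file.path(dir, f), row.names = FALSE)
    manifest$scales[[length(manifest$scales) + 1L]] <-
      list(scale_m = s, n_units = nrow(tab), file = f)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read unit tables previously written by [write_unit_tables()]
#'
#' @param dir Directory holding `units_*.csv`.
#' @return List of unit tables ordered by scale.
#' @export
read_unit_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "^units_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop_config(sprintf("no unit tables found under %s", dir),
                field = "dir")
  }
  lapply(files, function(f) {
    tab <- utils::read.csv(f)
    attr(tab, "scale_m") <- as.numeric(tab$scale_m[1])
    tab
  })
}
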
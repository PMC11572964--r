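#' Paired LST and canopy rasters
#'
#' Bundles a land-surface-temperature raster at the base analysis
#' resolution with a tree-canopy raster that is either (a) fractional
#' cover in `[0, 1]` on the same base grid, or (b) a binary (0/1) canopy
#' map at a strictly finer resolution whose pixel size divides the base
#' pixel size evenly. An optional boundary mask (1 = inside the study
#' area) on the base grid restricts all downstream aggregation.
#'
#' Construction validates co-registration: the two footprints must agree
#' to within half a base pixel, and the resolution ratio must be an exact
#' integer. No resampling is ever performed; misaligned inputs are
#' rejected rather than silently warped, because implicit resampling
#' would corrupt the scaling design.
#'
#' @param lst [raster_grid()] of LST in degrees Celsius.
#' @param canopy [raster_grid()] of canopy: fractional cover at base
#'   resolution or binary cover at a finer resolution.
#' @param boundary Optional [raster_grid()] 0/1 mask at base resolution.
#' @return An object of class `raster_pair` with elements `lst`, `canopy`,
#'   `boundary`, `canopy_kind` (`"fractional"` or `"binary"`), and `ratio`
#'   (base pixel size / canopy pixel size, an integer).
#' @export
raster_pair <- function(lst, canopy, boundary = NULL) {
  stopifnot(inherits(lst, "raster_grid"), inherits(canopy, "raster_grid"))

  ratio_raw <- lst$pixel_size / canopy$pixel_size
  ratio <- round(ratio_raw)
  if (ratio < 1 || abs(ratio_raw - ratio) > 1e-6) {
    stop_compute(
      sprintf(paste0("canopy resolution (%g m) does not evenly divide the ",
                     "base LST resolution (%g m): ratio %.6g is not an ",
                     "integer"),
              canopy$pixel_size, lst$pixel_size, ratio_raw),
      class = "canopycooler_ratio_error"
    )
  }

  half_px <- lst$pixel_size / 2
  d_origin <- max(abs(lst$origin - canopy$origin))
  ext_lst <- dim(lst$values) * lst$pixel_size          # (height, width) m
  ext_can <- dim(canopy$values) * canopy$pixel_size
  d_extent <- max(abs(ext_lst - ext_can))
  if (d_origin > half_px || d_extent > half_px) {
    stop_compute(
      sprintf(paste0("LST and canopy rasters do not share a footprint: ",
                     "origin offset %.3g m, extent mismatch %.3g m ",
                     "(tolerance: half a base pixel, %.3g m)"),
              d_origin, d_extent, half_px),
      class = "canopycooler_alignment_error"
    )
  }
  if (!all(dim(canopy$values) == dim(lst$values) * ratio)) {
    stop_compute(
      "canopy grid dimensions are not an integer multiple of the LST grid",
      class = "canopycooler_ratio_error"
    )
  }

  v <- canopy$values
  finite <- v[!is.na(v)]
  is_binary <- length(finite) > 0 && all(finite %in% c(0, 1))
  if (ratio > 1L && !is_binary) {
    stop_compute(
      "fine-resolution canopy must be binary (values 0/1/nodata)",
      class = "canopycooler_range_error"
    )
  }
  if (!is_binary && (any(finite < 0) || any(finite > 1))) {
    stop_compute(
      sprintf("fractional canopy cover outside [0, 1]: range [%.4g, %.4g]",
              min(finite), max(finite)),
      class = "canopycooler_range_error"
    )
  }

  if (!is.null(boundary)) {
    stopifnot(inherits(boundary, "raster_grid"))
    if (!all(dim(boundary$values) == dim(lst$values))) {
      stop_compute("boundary mask must match the base LST grid",
                   class = "canopycooler_alignment_error")
    }
  }

  structure(
    list(lst = lst, canopy = canopy, boundary = boundary,
         canopy_kind = if (is_binary) "binary" else "fractional",
         ratio = as.integer(ratio)),
    class = "raster_pair"
  )
}

#' @export
print.raster_pair <- function(x, ...) {
  cat(sprintf(
    "<raster_pair> LST %d x %d px @ %g m; canopy %s @ %g m (ratio %d)%s\n",
    nrow(x$lst$values), ncol(x$lst$values), x$lst$pixel_size,
    x$canopy_kind, x$canopy$pixel_size, x$ratio,
    if (is.null(x$boundary)) "" else "; boundary mask"))
  invisible(x)
}

#' Load a co-registered LST / canopy raster pair from ASCII grids
#'
#' Reads the two rasters (plus an optional 0/1 boundary mask on the base
#' grid), validates co-registration and value ranges, auto-detects whether
#' the canopy raster is binary, and reports the resolution ratio.
#'
#' @param lst_path,canopy_path Paths to Esri ASCII grid files.
#' @param boundary_path Optional path to a 0/1 ASCII grid mask.
#' @param crs_id CRS identifier attached to all grids (must be shared;
#'   the ASCII format itself carries none).
#' @param quiet Suppress the resolution-ratio message.
#' @return A [raster_pair()].
#' @export
load_raster_pair <- function(lst_path, canopy_path, boundary_path = NULL,
                             crs_id = "local", quiet = FALSE) {
  lst <- read_ascii_grid(lst_path, crs_id = crs_id)
  canopy <- read_ascii_grid(canopy_path, crs_id = crs_id)
  boundary <- if (!is.null(boundary_path)) {
    read_ascii_grid(boundary_path, crs_id = crs_id)
  }
  pair <- raster_pair(lst, canopy, boundary)
  if (!quiet) {
    message(sprintf("loaded raster pair: canopy/LST resolution ratio %d (%s)",
                    pair$ratio, pair$canopy_kind))
  }
  pair
}

#' Coarsen a fine binary canopy map to fractional cover at base resolution
#'
#' Each base cell's cover is the fraction of its fine canopy pixels equal
#' to 1, ignoring fine nodata pixels; base cells with more than 50% fine
#' nodata become nodata themselves. A pair already holding fractional
#' cover at base resolution is returned unchanged.
#'
#' @param pair A [raster_pair()].
#' @return A [raster_pair()] whose canopy is fractional cover on the base
#'   grid.
#' @export
coarsen_canopy <- function(pair) {
  stopifnot(inherits(pair, "raster_pair"))
  if (pair$ratio == 1L && pair$canopy_kind == "fractional") return(pair)
  if (pair$ratio == 1L) {
    # binary already at base resolution: 0/1 is valid fractional cover
    out <- pair
    out$canopy_kind <- "fractional"
    return(out)
  }
  w <- pair$ratio
  bs <- block_stats(pair$canopy$values, w)
  cover <- bs$sum / bs$n_valid
  cover[bs$n_valid < (w * w) / 2] <- NA_real_   # >50% fine nodata
  cover_grid <- raster_grid(cover, pixel_size = pair$lst$pixel_size,
                            origin = pair$canopy$origin,
                            crs_id = pair$canopy$crs_id)
  raster_pair(pair$lst, cover_grid, pair$boundary)
}

# Block-aggregate a matrix into w x w tiles anchored at [1, 1]; partial
# tiles at the right/bottom edges are discarded. Returns per-tile sums
# over non-NA cells and the count of non-NA cells.
block_stats <- function(m, w) {
  nr <- nrow(m) %/% w
  nc <- ncol(m) %/% w
  if (nr == 0L || nc == 0L) {
    return(list(sum = matrix(numeric(0), 0, 0),
                n_valid = matrix(numeric(0), 0, 0)))
  }
  m <- m[seq_len(nr * w), seq_len(nc * w), drop = FALSE]
  valid <- !is.na(m)
  m0 <- m
  m0[!valid] <- 0
  rg <- rep(seq_len(nr), each = w)
  cg <- rep(seq_len(nc), each = w)
  agg <- function(x) {
    out <- t(rowsum(t(rowsum(x, rg, reorder = FALSE)),
                    cg, reorder = FALSE))
    dimnames(out) <- NULL
    out
  }
  list(sum = agg(m0), n_valid = agg(valid + 0))
}
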
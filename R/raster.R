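#' Raster grid container
#'
#' A minimal single-band raster: a numeric matrix in row-major image
#' convention (row 1 is the northernmost row, pixel centres at
#' (col + 0.5, row + 0.5) in pixel space), a square pixel size in metres,
#' the map coordinate of the grid's top-left corner, and a free-form
#' coordinate-system identifier. Missing cells are `NA`.
#'
#' @param values Numeric matrix, row 1 = top row.
#' @param pixel_size Pixel edge length in metres (> 0).
#' @param origin Length-2 numeric, map (x, y) of the top-left corner.
#' @param crs_id Coordinate-system identifier (not interpreted; carried
#'   through for bookkeeping).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, pixel_size, origin = c(0, 0),
                        crs_id = "local") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_config("`values` must be a numeric matrix", field = "values")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop_config("`pixel_size` must be a single positive number",
                field = "pixel_size")
  }
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs_id = as.character(crs_id)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d px, %.6g m/px, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$pixel_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%.4g, %.4g], %d NA\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Write a raster grid as an Esri ASCII grid (.asc)
#'
#' Plain-text raster format: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values from north
#' to south. `NA` cells are written as the nodata value. The CRS identifier
#' is not representable in this format and is dropped on write.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits used when formatting values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 15) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  xll <- grid$origin[1]
  yll <- grid$origin[2] - nr * grid$pixel_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  out <- v
  out[is.na(out)] <- nodata
  body <- apply(out, 1L, function(row) {
    paste(formatC(row, format = "g", digits = digits), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid (.asc) into a raster grid
#'
#' @param path File path.
#' @param crs_id CRS identifier to attach (the format itself carries none).
#' @return A [raster_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, crs_id = "local") {
  if (!file.exists(path)) {
    stop_config(sprintf("raster file not found: %s", path), field = "path")
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_config(sprintf("malformed ASCII grid header in %s", path),
                field = "path")
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop_config(sprintf("ASCII grid %s has %d values, expected %d",
                        path, length(vals), nr * nc), field = "path")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  raster_grid(m, pixel_size = hdr$cellsize,
              origin = c(xll, yll + nr * hdr$cellsize), crs_id = crs_id)
}

# condition helpers: validation errors carry class "canopycooler_config_error"
# so callers can distinguish bad inputs from computation failures
stop_config <- function(msg, field = NULL) {
  stop(errorCondition(
    if (is.null(field)) msg else sprintf("%s [field: %s]", msg, field),
    class = c("canopycooler_config_error", "canopycooler_error")
  ))
}

stop_compute <- function(msg, class) {
  stop(errorCondition(
    msg, class = c(class, "canopycooler_error")
  ))
}
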
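#' Grid specification for a georeferenced raster
#'
#' A `grid_spec` describes a regular grid of square cells in a projected
#' (equal-area or otherwise metric) coordinate system.  Cell `(r, c)`
#' (1-based in R, row 1 at the top) covers the half-open square
#' `[x_origin + (c-1)*s, x_origin + c*s) x (y_origin - r*s, y_origin - (r-1)*s]`
#' where `s = cell_size_m`.  Geographic (degree) grids must be projected
#' before use; the pipeline treats `cell_size_m` as a true metric distance.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_size_m positive real, edge length of the square cells in
#'   meters.
#' @param x_origin,y_origin coordinates of the upper-left corner of the grid
#'   (the top-left corner of cell (1,1)).
#' @param crs_id opaque coordinate-reference-system label, carried through
#'   I/O but never interpreted.
#' @param nodata sentinel value used on disk for missing cells.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_m,
                      x_origin = 0, y_origin = n_rows * cell_size_m,
                      crs_id = "local-metric", nodata = -9999) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1L, n_cols >= 1L,
            is.numeric(cell_size_m), length(cell_size_m) == 1L,
            cell_size_m > 0,
            is.finite(x_origin), is.finite(y_origin), is.finite(nodata))
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size_m = as.numeric(cell_size_m),
                 x_origin = as.numeric(x_origin),
                 y_origin = as.numeric(y_origin),
                 crs_id = as.character(crs_id),
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g m, origin (%.6g, %.6g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$x_origin, x$y_origin,
              x$crs_id))
  invisible(x)
}

.RASTER_KINDS <- c("friction", "population", "travel_time", "zone", "mask",
                   "heatmap_class")
.INTEGER_KINDS <- c("zone", "mask", "heatmap_class")

#' Construct a raster bound to a grid specification
#'
#' In memory, nodata cells are `NA`; for `travel_time` rasters `Inf` marks
#' cells unreachable over passable terrain (both become the nodata sentinel
#' on disk, and nodata reads back as `Inf` for this kind).
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix of dimension `n_rows x n_cols` (row 1 = top),
#'   or a single value to fill the grid.
#' @param kind one of `"friction"` (minutes per meter), `"population"`
#'   (persons per cell), `"travel_time"` (minutes), `"zone"`, `"mask"`,
#'   `"heatmap_class"`.
#' @param validate check kind invariants (positive friction, non-negative
#'   finite population, 0/1 mask, ...).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(spec, values, kind, validate = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  kind <- match.arg(kind, .RASTER_KINDS)
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  if (!is.matrix(values) || nrow(values) != spec$n_rows ||
      ncol(values) != spec$n_cols)
    stop("values must be a ", spec$n_rows, " x ", spec$n_cols, " matrix")
  storage.mode(values) <- "double"
  x <- structure(list(spec = spec, values = values, kind = kind),
                 class = "grid_raster")
  if (validate) validate_raster(x)
  x
}

#' Check a raster's kind invariants
#'
#' @param x a [grid_raster()].
#' @return `x`, invisibly; errors name the first offending cell.
#' @export
validate_raster <- function(x) {
  stopifnot(inherits(x, "grid_raster"))
  v <- x$values
  bad <- switch(x$kind,
    friction    = which(!is.na(v) & (!is.finite(v) | v <= 0)),
    population  = which(!is.na(v) & (!is.finite(v) | v < 0)),
    travel_time = which(!is.na(v) & (is.nan(v) | v < 0)),
    mask        = which(!is.na(v) & !(v %in% c(0, 1))),
    which(!is.na(v) & (!is.finite(v) | v < 0 | v != round(v))))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(v))
    stop(sprintf("invalid %s value %g at cell (row %d, col %d)",
                 x$kind, v[bad[1L]], rc[1L], rc[2L]))
  }
  invisible(x)
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grid_raster:%s> %d x %d; finite range [%.6g, %.6g]; %d nodata\n",
              x$kind, x$spec$n_rows, x$spec$n_cols,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Test whether two rasters share one grid
#'
#' Two rasters are aligned iff all `grid_spec` fields except the nodata
#' sentinel are equal.  Every multi-raster operation in the pipeline
#' requires alignment and errors otherwise.
#'
#' @param a,b [grid_raster()] or [grid_spec()] objects.
#' @return logical scalar.
#' @export
align_check <- function(a, b) {
  sa <- if (inherits(a, "grid_raster")) a$spec else a
  sb <- if (inherits(b, "grid_raster")) b$spec else b
  stopifnot(inherits(sa, "grid_spec"), inherits(sb, "grid_spec"))
  isTRUE(sa$n_rows == sb$n_rows) && isTRUE(sa$n_cols == sb$n_cols) &&
    isTRUE(sa$cell_size_m == sb$cell_size_m) &&
    isTRUE(sa$x_origin == sb$x_origin) &&
    isTRUE(sa$y_origin == sb$y_origin) &&
    isTRUE(sa$crs_id == sb$crs_id)
}

.require_aligned <- function(a, b, what = "rasters") {
  if (!align_check(a, b))
    stop("misaligned ", what,
         ": grids must share shape, cell size, origin and CRS")
  invisible(TRUE)
}

#' Map projected coordinates to grid cells
#'
#' @param spec a [grid_spec()].
#' @param x,y projected coordinates.
#' @return integer matrix with columns `row`, `col` (1-based); coordinates
#'   outside the grid give `NA`.
#' @export
xy_to_cell <- function(spec, x, y) {
  s <- spec$cell_size_m
  col <- floor((x - spec$x_origin) / s) + 1
  row <- floor((spec$y_origin - y) / s) + 1
  # the grid's outer edge belongs to the last row/col (closed outer boundary)
  col[x == spec$x_origin + spec$n_cols * s] <- spec$n_cols
  row[y == spec$y_origin - spec$n_rows * s] <- spec$n_rows
  out <- cbind(row = as.integer(row), col = as.integer(col))
  bad <- out[, 1L] < 1L | out[, 1L] > spec$n_rows |
         out[, 2L] < 1L | out[, 2L] > spec$n_cols
  out[bad, ] <- NA_integer_
  out
}

#' Centers of grid cells
#'
#' @param spec a [grid_spec()].
#' @param row,col 1-based indices.
#' @return matrix with columns `x`, `y`.
#' @export
cell_center <- function(spec, row, col) {
  s <- spec$cell_size_m
  cbind(x = spec$x_origin + (col - 0.5) * s,
        y = spec$y_origin - (row - 0.5) * s)
}

#' Read a single-band GeoTIFF
#'
#' Supports uncompressed classic TIFF, single band, integer or IEEE-float
#' samples, either byte order.  The file's geotransform must describe square
#' cells (x and y pixel sizes equal to within 1e-6 relative).
#'
#' @param path file path.
#' @param kind raster kind, see [grid_raster()].
#' @return a validated [grid_raster()].
#' @export
read_raster <- function(path, kind) {
  kind <- match.arg(kind, .RASTER_KINDS)
  if (!file.exists(path)) stop("raster file not found: ", path)
  t <- .tiff_read(path)
  ps <- t$pixel_scale
  if (is.null(ps) || length(ps) < 2L)
    stop("GeoTIFF lacks a pixel-scale geotransform: ", path)
  if (abs(ps[1L] - ps[2L]) > 1e-6 * max(abs(ps[1L]), abs(ps[2L])))
    stop(sprintf(
      "non-square cells (%.9g x %.9g m); reproject to a square metric grid: %s",
      ps[1L], ps[2L], path))
  tp <- t$tiepoint
  if (is.null(tp) || length(tp) < 6L)
    stop("GeoTIFF lacks a tiepoint: ", path)
  x_origin <- tp[4L] - tp[1L] * ps[1L]
  y_origin <- tp[5L] + tp[2L] * ps[2L]
  nodata <- if (!is.null(t$nodata)) as.numeric(t$nodata) else -9999
  crs <- if (!is.null(t$crs)) sub("\\|+$", "", t$crs) else "unknown"
  spec <- grid_spec(t$height, t$width, ps[1L], x_origin, y_origin, crs,
                    nodata)
  vals <- t$values
  vals[vals == nodata | is.nan(vals)] <- NA_real_
  if (kind == "travel_time") vals[is.na(vals)] <- Inf
  grid_raster(spec, vals, kind)
}

#' Write a raster as a single-band GeoTIFF
#'
#' Float kinds are stored as 64-bit floats so `read_raster(write_raster(x))`
#' is the identity bit-for-bit; `zone`, `mask` and `heatmap_class` rasters
#' are stored as 32-bit integers.  `NA` cells, and `Inf` cells of a
#' `travel_time` raster, become the spec's nodata sentinel.
#'
#' @param raster a validated [grid_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "grid_raster"))
  validate_raster(raster)
  spec <- raster$spec
  vals <- raster$values
  vals[is.na(vals) | is.infinite(vals)] <- spec$nodata
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  .tiff_write(path, vals,
              pixel_scale = c(spec$cell_size_m, spec$cell_size_m, 0),
              tiepoint = c(0, 0, 0, spec$x_origin, spec$y_origin, 0),
              nodata_str = format(spec$nodata, digits = 17),
              crs = spec$crs_id,
              integer_band = raster$kind %in% .INTEGER_KINDS)
  invisible(path)
}
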
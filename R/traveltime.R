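#' Bind facilities to friction-grid cells
#'
#' Each facility maps to the cell containing its point.  Facilities landing
#' on an impassable (nodata) friction cell are snapped to the nearest
#' passable cell within `snap_radius` cells (Euclidean point-to-center
#' distance, ties broken on lowest row then column); facilities outside the
#' grid or with no passable cell in range are reported unplaceable, not
#' fatal.  Multiple facilities may share one source cell.
#'
#' @param fs a [facility_set()] with coordinates in the grid's CRS.
#' @param friction friction [grid_raster()] (provides the grid).
#' @param snap_radius snap search radius in cells (Chebyshev), default 5.
#' @return object of class `source_cells`: list with `cells` (unique
#'   `row`/`col` data frame), `mapping` (per facility: `id`, `row`, `col`,
#'   `snapped`), `unplaced` (ids), and the grid `spec`.
#' @export
rasterize_facilities <- function(fs, friction, snap_radius = 5L) {
  stopifnot(inherits(fs, "facility_set"), inherits(friction, "grid_raster"),
            friction$kind == "friction")
  spec <- friction$spec
  f <- fs$facilities
  rc <- xy_to_cell(spec, f$x, f$y)
  ids <- character(0); rows <- integer(0); cols <- integer(0)
  snapped <- logical(0); unplaced <- character(0)
  for (i in seq_len(nrow(f))) {
    r <- rc[i, 1L]; c <- rc[i, 2L]
    if (is.na(r)) { unplaced <- c(unplaced, f$id[i]); next }
    was_snapped <- FALSE
    if (is.na(friction$values[r, c])) {
      cand <- .snap_to_passable(spec, friction$values, f$x[i], f$y[i],
                                r, c, snap_radius)
      if (is.null(cand)) { unplaced <- c(unplaced, f$id[i]); next }
      r <- cand[1L]; c <- cand[2L]; was_snapped <- TRUE
    }
    ids <- c(ids, f$id[i]); rows <- c(rows, r); cols <- c(cols, c)
    snapped <- c(snapped, was_snapped)
  }
  mapping <- data.frame(id = ids, row = rows, col = cols, snapped = snapped,
                        stringsAsFactors = FALSE)
  cells <- unique(mapping[, c("row", "col")])
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, mapping = mapping, unplaced = unplaced,
                 spec = spec),
            class = "source_cells")
}

.snap_to_passable <- function(spec, fvals, px, py, r0, c0, radius) {
  rs <- max(1L, r0 - radius):min(spec$n_rows, r0 + radius)
  cs <- max(1L, c0 - radius):min(spec$n_cols, c0 + radius)
  grid <- expand.grid(row = rs, col = cs)
  ok <- !is.na(fvals[cbind(grid$row, grid$col)])
  if (!any(ok)) return(NULL)
  grid <- grid[ok, , drop = FALSE]
  ctr <- cell_center(spec, grid$row, grid$col)
  d2 <- (ctr[, 1L] - px)^2 + (ctr[, 2L] - py)^2
  grid <- grid[order(d2, grid$row, grid$col), , drop = FALSE]
  c(grid$row[1L], grid$col[1L])
}

#' @export
print.source_cells <- function(x, ...) {
  cat(sprintf("<source_cells> %d cells from %d facilities (%d snapped, %d unplaced)\n",
              nrow(x$cells), nrow(x$mapping), sum(x$mapping$snapped),
              length(x$unplaced)))
  invisible(x)
}

#' Accumulate least-cost travel time from source cells
#'
#' Single-run multi-source Dijkstra over the friction grid: the travel time
#' of a cell is the minimum over paths from any source of the summed edge
#' costs, where the edge between adjacent cells `a`, `b` costs
#' `((f(a)+f(b))/2) * d(a,b)` with `d` equal to the cell size for the 4
#' orthogonal neighbors, `cell_size*sqrt(2)` for the 4 diagonal neighbors
#' (8-connectivity, the default), and `cell_size*sqrt(5)` for knight moves
#' under 16-connectivity.  Nodata friction cells are impassable.  Heap ties
#' break on lowest `(row, col)` so results are bit-reproducible.
#'
#' @param friction friction [grid_raster()], minutes per meter (or minutes
#'   per cell with `friction_units = "min_per_cell"`, divided by the cell
#'   size on entry).
#' @param sources a [rasterize_facilities()] result, or a 2-column
#'   `row`/`col` matrix/data frame of source cells on the same grid.
#' @param connectivity 4, 8 or 16.
#' @param friction_units `"min_per_m"` (default) or `"min_per_cell"`.
#' @return travel-time [grid_raster()] in minutes: 0 at sources, `Inf` for
#'   unreachable passable cells, `NA` on nodata friction.
#' @export
accumulate_cost <- function(friction, sources, connectivity = 8L,
                            friction_units = c("min_per_m", "min_per_cell")) {
  stopifnot(inherits(friction, "grid_raster"), friction$kind == "friction")
  friction_units <- match.arg(friction_units)
  cells <- .source_cell_df(friction, sources)
  if (nrow(cells) == 0L) stop("source set is empty")
  fvals <- friction$values
  if (friction_units == "min_per_cell")
    fvals <- fvals / friction$spec$cell_size_m
  tt <- .dijkstra_accumulate(fvals,
                             as.integer(cells$row) - 1L,
                             as.integer(cells$col) - 1L,
                             friction$spec$cell_size_m,
                             as.integer(connectivity))
  grid_raster(friction$spec, tt, "travel_time")
}

.source_cell_df <- function(friction, sources) {
  if (inherits(sources, "source_cells")) {
    .require_aligned(friction$spec, sources$spec, "friction and sources")
    return(sources$cells)
  }
  cells <- as.data.frame(sources)
  if (!all(c("row", "col") %in% names(cells))) {
    if (ncol(cells) == 2L) names(cells) <- c("row", "col")
    else stop("sources must have row and col columns")
  }
  spec <- friction$spec
  if (nrow(cells) &&
      (any(cells$row < 1L | cells$row > spec$n_rows) ||
       any(cells$col < 1L | cells$col > spec$n_cols)))
    stop("source cell out of grid bounds")
  cells
}

#' Reference travel-time accumulation by edge relaxation
#'
#' Independent test oracle for [accumulate_cost()]: repeated Bellman-Ford
#' relaxation over the identical edge set until fixpoint, in plain R.
#' Guarded to grids of at most 64 x 64 cells; intended for tests only.
#'
#' @inheritParams accumulate_cost
#' @return travel-time [grid_raster()] under the same contract.
#' @export
oracle_accumulate <- function(friction, sources, connectivity = 8L) {
  stopifnot(inherits(friction, "grid_raster"), friction$kind == "friction")
  spec <- friction$spec
  if (spec$n_rows > 64L || spec$n_cols > 64L)
    stop("oracle guard: grid larger than 64 x 64")
  cells <- .source_cell_df(friction, sources)
  if (nrow(cells) == 0L) stop("source set is empty")
  nr <- spec$n_rows; nc <- spec$n_cols; s <- spec$cell_size_m
  fv <- friction$values

  off <- rbind(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1))
  if (connectivity >= 8L)
    off <- rbind(off, cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1), sqrt(2)))
  if (connectivity == 16L)
    off <- rbind(off, cbind(c(-2, -2, -1, -1, 1, 1, 2, 2),
                            c(-1, 1, -2, 2, -2, 2, -1, 1), sqrt(5)))

  # directed edge list over passable cells (column-major linear ids)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  pass <- !is.na(fv)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1L]; dc <- off[k, 2L]; step <- off[k, 3L]
    rlo <- max(1, 1 - dr); rhi <- min(nr, nr - dr)
    clo <- max(1, 1 - dc); chi <- min(nc, nc - dc)
    if (rlo > rhi || clo > chi) next
    g <- expand.grid(r = rlo:rhi, c = clo:chi)
    r2 <- g$r + dr; c2 <- g$c + dc
    ok <- pass[cbind(g$r, g$c)] & pass[cbind(r2, c2)]
    if (!any(ok)) next
    a <- (g$c[ok] - 1L) * nr + g$r[ok]
    b <- (c2[ok] - 1L) * nr + r2[ok]
    from <- c(from, a); to <- c(to, b)
    # same operation order as the Dijkstra edge cost, so path sums agree
    # bit-for-bit
    w <- c(w, 0.5 * (fv[a] + fv[b]) * step * s)
  }

  d <- rep(Inf, nr * nc)
  d[(cells$col - 1L) * nr + cells$row] <- 0
  if (any(!pass[cbind(cells$row, cells$col)]))
    stop("source cell sits on impassable (nodata) friction")
  tof <- factor(to, levels = seq_len(nr * nc))
  repeat {
    cand <- d[from] + w
    best <- tapply(cand, tof, min)
    best[is.na(best)] <- Inf
    nd <- pmin(d, as.numeric(best))
    if (identical(nd, d)) break
    d <- nd
  }
  d[!pass] <- NA_real_
  grid_raster(spec, matrix(d, nr, nc), "travel_time")
}
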
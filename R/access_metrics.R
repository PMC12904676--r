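# Travel-time comparisons against thresholds are inclusive: "within 30
# minutes" means tt <= 30.  Inf travel time (unreachable) counts as not
# covered at every threshold and sits in the upper quantile tail; NA travel
# time (outside the modelled domain) also counts as not covered, so
# population conservation (covered + red zone = total) holds on every grid.

.stratum_logical <- function(tt, stratum_mask) {
  if (is.null(stratum_mask)) {
    matrix(TRUE, tt$spec$n_rows, tt$spec$n_cols)
  } else if (inherits(stratum_mask, "grid_raster")) {
    .require_aligned(tt, stratum_mask, "travel-time and stratum rasters")
    !is.na(stratum_mask$values) & stratum_mask$values == 1
  } else {
    m <- stratum_mask
    stopifnot(is.matrix(m), nrow(m) == tt$spec$n_rows,
              ncol(m) == tt$spec$n_cols)
    if (!is.logical(m)) m <- !is.na(m) & m == 1
    m & !is.na(m)
  }
}

#' Binary accessibility raster
#'
#' @param tt travel-time [grid_raster()].
#' @param threshold_min positive threshold in minutes; the comparison is
#'   inclusive (`tt <= threshold`).
#' @return mask [grid_raster()]: 1 within the threshold, 0 outside
#'   (including unreachable cells), `NA` where travel time is `NA`.
#' @export
binary_access_mask <- function(tt, threshold_min) {
  stopifnot(inherits(tt, "grid_raster"), tt$kind == "travel_time",
            is.numeric(threshold_min), length(threshold_min) == 1L,
            threshold_min > 0)
  v <- ifelse(is.na(tt$values), NA_real_,
              as.numeric(tt$values <= threshold_min))
  grid_raster(tt$spec, v, "mask")
}

#' Access population coverage (APC)
#'
#' Percentage of a stratum's population living in cells whose travel time
#' to the nearest facility is within the threshold.
#'
#' @param tt travel-time [grid_raster()].
#' @param pop population [grid_raster()] on the same grid.
#' @param threshold_min threshold in minutes (inclusive).
#' @param stratum_mask optional mask [grid_raster()] or logical matrix
#'   restricting the stratum; `NULL` means all cells.
#' @return percentage in `[0, 100]`, unrounded; `NA` with a warning when
#'   the stratum holds no population.
#' @export
apc <- function(tt, pop, threshold_min, stratum_mask = NULL) {
  stopifnot(inherits(tt, "grid_raster"), tt$kind == "travel_time",
            inherits(pop, "grid_raster"), pop$kind == "population")
  .require_aligned(tt, pop, "travel-time and population rasters")
  inc <- .stratum_logical(tt, stratum_mask) & !is.na(pop$values)
  denom <- sum(pop$values[inc])
  if (denom <= 0) {
    warning("stratum has zero population; APC undefined")
    return(NA_real_)
  }
  covered <- inc & !is.na(tt$values) & tt$values <= threshold_min
  100 * sum(pop$values[covered]) / denom
}

# weighted quantile: smallest value v whose cumulative weight reaches
# p * W (left-continuous step inverse); Inf values sort to the tail
.weighted_quantile <- function(v, w, probs) {
  ord <- order(v)
  v <- v[ord]; w <- w[ord]
  cw <- cumsum(w)
  W <- cw[length(cw)]
  vapply(probs, function(p) v[which(cw >= p * W)[1L]], numeric(1))
}

#' Stratified travel-time summary
#'
#' Mean, SD, median and quartiles of travel time over a stratum, either
#' population-weighted (cells with positive population, weight = cell
#' population; the default) or per pixel (all non-`NA` travel-time cells,
#' equal weight).  Unreachable (`Inf`) cells participate: quantiles stay
#' finite while the unreachable weight fraction is below the quantile
#' level, and mean/SD become `Inf` when any unreachable weight is present.
#'
#' @param tt travel-time [grid_raster()].
#' @param pop population [grid_raster()]; required for population
#'   weighting.
#' @param stratum_mask optional mask raster or logical matrix.
#' @param weighting `"population"` or `"pixel"`.
#' @return named numeric: `mean`, `sd`, `median`, `q1`, `q3`, `n_cells`,
#'   `weight`.
#' @export
travel_time_summary <- function(tt, pop = NULL, stratum_mask = NULL,
                                weighting = c("population", "pixel")) {
  stopifnot(inherits(tt, "grid_raster"), tt$kind == "travel_time")
  weighting <- match.arg(weighting)
  inc <- .stratum_logical(tt, stratum_mask) & !is.na(tt$values)
  if (weighting == "population") {
    if (is.null(pop)) stop("population raster required for population weighting")
    stopifnot(inherits(pop, "grid_raster"), pop$kind == "population")
    .require_aligned(tt, pop, "travel-time and population rasters")
    inc <- inc & !is.na(pop$values) & pop$values > 0
    w <- pop$values[inc]
  } else {
    w <- rep(1, sum(inc))
  }
  v <- tt$values[inc]
  if (!length(v) || sum(w) <= 0) stop("empty stratum: no contributing cells")
  W <- sum(w)
  m <- sum(w * v) / W
  s2 <- sum(w * (v - m)^2) / W
  q <- .weighted_quantile(v, w, c(0.25, 0.5, 0.75))
  c(mean = m, sd = sqrt(s2), median = q[2L], q1 = q[1L], q3 = q[3L],
    n_cells = length(v), weight = W)
}

#' Population beyond a travel-time threshold ("red zone")
#'
#' Total population in cells whose travel time exceeds the threshold
#' (including unreachable and out-of-domain cells), i.e. the complement of
#' the covered population: `red_zone + covered = total`.
#'
#' @param tt travel-time [grid_raster()].
#' @param pop population [grid_raster()].
#' @param threshold_min threshold in minutes, default 60 (the conventional
#'   one-hour deprivation line).
#' @return summed population.
#' @export
red_zone_population <- function(tt, pop, threshold_min = 60) {
  stopifnot(inherits(tt, "grid_raster"), tt$kind == "travel_time",
            inherits(pop, "grid_raster"), pop$kind == "population")
  .require_aligned(tt, pop, "travel-time and population rasters")
  ok <- !is.na(pop$values)
  covered <- ok & !is.na(tt$values) & tt$values <= threshold_min
  sum(pop$values[ok]) - sum(pop$values[covered])
}

#' Classify travel time into four heatmap bands
#'
#' Band 1 (blue): `tt <= 15`; 2 (green): `15 < tt <= 30`; 3 (yellow):
#' `30 < tt <= 60`; 4 (red): `tt > 60` (including unreachable).  `NA`
#' propagates.
#'
#' @param tt travel-time [grid_raster()].
#' @return `heatmap_class` [grid_raster()] with codes 1-4.
#' @export
classify_heatmap <- function(tt) {
  stopifnot(inherits(tt, "grid_raster"), tt$kind == "travel_time")
  v <- tt$values
  cls <- ifelse(is.na(v), NA_real_,
         ifelse(v <= 15, 1, ifelse(v <= 30, 2, ifelse(v <= 60, 3, 4))))
  grid_raster(tt$spec, cls, "heatmap_class")
}

#' Color table for heatmap class rasters
#' @return data frame mapping classes 1-4 to color names and hex codes.
#' @export
heatmap_color_table <- function() {
  data.frame(class = 1:4,
             color = c("blue", "green", "yellow", "red"),
             hex = c("#2166AC", "#1A9850", "#FEE08B", "#D73027"),
             band = c("<=15 min", "15-30 min", "30-60 min", ">60 min"),
             stringsAsFactors = FALSE)
}

#' Stratified access report
#'
#' One row per (national + each zone) x (total, rural, urban): stratum
#' population, travel-time mean (SD) and median (IQR), and APC at each
#' threshold.  Minutes and percentages are rounded half-up to one decimal;
#' strata with zero population are flagged, not dropped.
#'
#' @param tt travel-time [grid_raster()].
#' @param pop population [grid_raster()].
#' @param zone_raster optional zone [grid_raster()] (integer codes).
#' @param urban_mask optional urban mask [grid_raster()]; rural is its
#'   complement over non-`NA` cells.
#' @param thresholds strictly increasing positive thresholds in minutes.
#' @param weighting summary weighting, see [travel_time_summary()].
#' @return data frame of class `access_report`.
#' @export
build_report <- function(tt, pop, zone_raster = NULL, urban_mask = NULL,
                         thresholds = c(30, 60, 120),
                         weighting = c("population", "pixel")) {
  stopifnot(inherits(tt, "grid_raster"), inherits(pop, "grid_raster"))
  weighting <- match.arg(weighting)
  if (!(length(thresholds) >= 1L && all(thresholds > 0) &&
        !is.unsorted(thresholds, strictly = TRUE)))
    stop("thresholds must be strictly increasing and positive")
  .require_aligned(tt, pop)
  if (!is.null(zone_raster)) .require_aligned(tt, zone_raster)
  if (!is.null(urban_mask)) .require_aligned(tt, urban_mask)

  zones <- if (is.null(zone_raster)) "national" else
    c("national", sort(unique(stats::na.omit(as.vector(zone_raster$values)))))
  settlements <- if (is.null(urban_mask)) "total" else
    c("total", "rural", "urban")

  all_true <- matrix(TRUE, tt$spec$n_rows, tt$spec$n_cols)
  rows <- list()
  for (z in zones) {
    zmask <- if (identical(z, "national")) all_true else
      !is.na(zone_raster$values) & zone_raster$values == as.numeric(z)
    for (s in settlements) {
      smask <- switch(s,
        total = zmask,
        urban = zmask & !is.na(urban_mask$values) & urban_mask$values == 1,
        rural = zmask & !is.na(urban_mask$values) & urban_mask$values == 0)
      stratum_pop <- sum(pop$values[smask & !is.na(pop$values)])
      flagged <- stratum_pop <= 0
      if (!flagged) {
        sm <- travel_time_summary(tt, pop, smask, weighting)
        apcs <- vapply(thresholds, function(th)
          round_half_up(apc(tt, pop, th, smask), 1L), numeric(1))
        row <- data.frame(zone = as.character(z), settlement = s,
                          population = stratum_pop,
                          mean_tt = round_half_up(sm[["mean"]], 1L),
                          sd_tt = round_half_up(sm[["sd"]], 1L),
                          median_tt = round_half_up(sm[["median"]], 1L),
                          q1_tt = round_half_up(sm[["q1"]], 1L),
                          q3_tt = round_half_up(sm[["q3"]], 1L),
                          stringsAsFactors = FALSE)
      } else {
        row <- data.frame(zone = as.character(z), settlement = s,
                          population = stratum_pop, mean_tt = NA_real_,
                          sd_tt = NA_real_, median_tt = NA_real_,
                          q1_tt = NA_real_, q3_tt = NA_real_,
                          stringsAsFactors = FALSE)
        apcs <- rep(NA_real_, length(thresholds))
      }
      for (k in seq_along(thresholds))
        row[[paste0("apc_", thresholds[k])]] <- apcs[k]
      row$flagged <- flagged
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("access_report", "data.frame")
  out
}
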
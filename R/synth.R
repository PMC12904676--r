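# Seeded generator for a miniature "country": friction surface with fast
# road corridors over a rougher background, population with dense urban
# clusters on a sparse rural majority, Voronoi zones of unequal facility
# endowment (one favored high-density zone), and facility tiers of
# increasing abundance and decreasing urban bias.  Every operation is a
# pure function of the config (integer-seeded base RNG, no time
# dependence), so identical configs give byte-identical worlds.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of the synthetic world
#'
#' Defaults describe a 96 x 96 km country at 1 km resolution with 6 zones,
#' 8 urban clusters holding 30% of a 5-million population (a rural-majority
#' country), road corridors at 50 km/h (0.0012 min/m) over a 6 km/h
#' off-road background (0.01 min/m) roughening to 1.5 km/h terrain
#' (0.04 min/m), and ~490 facilities whose tier abundances rise and urban
#' bias falls from teaching hospitals down to primary health centres.  The
#' directory tier (PCC) concentrates 44.5% of its centres in the favored
#' zone, emulating a one-state concentration of specialised centres.
#'
#' @param seed integer master seed.
#' @param n_rows,n_cols,cell_size_m grid shape, see [grid_spec()].
#' @param n_zones number of Voronoi zones.
#' @param n_urban_clusters number of urban population kernels.
#' @param total_population total persons on the grid.
#' @param urban_share fraction of population in urban clusters, in (0,1).
#' @param road_count number of road corridors.
#' @param road_friction,offroad_friction,rough_friction minutes per meter,
#'   strictly increasing.
#' @param roughness_amplitude multiplicative log-scale roughness strength
#'   (0 disables terrain roughening).
#' @param facility_counts named integer vector per tier.
#' @param urban_bias named fraction per tier placed in urban cells.
#' @param favored_zone zone code receiving the PCC surplus.
#' @param favored_share fraction of PCC centres placed in the favored zone.
#' @param service_probs named list of `c(yes, no, unknown)` probabilities
#'   per tri-state service flag, plus `cost` as
#'   `c(free, free_for_poor, paid, unknown)`.
#' @param crs_id,nodata passed to [grid_spec()].
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 42L, n_rows = 96L, n_cols = 96L,
                         cell_size_m = 1000,
                         n_zones = 6L, n_urban_clusters = 8L,
                         total_population = 5e6, urban_share = 0.3,
                         road_count = 12L,
                         road_friction = 0.0012, offroad_friction = 0.01,
                         rough_friction = 0.04, roughness_amplitude = 0.6,
                         facility_counts = c(PCC = 60L, TH = 8L, DH = 15L,
                                             CHC = 60L, PHC = 350L),
                         urban_bias = c(PCC = 0.7, TH = 0.9, DH = 0.7,
                                        CHC = 0.4, PHC = 0.2),
                         favored_zone = 1L, favored_share = 0.445,
                         service_probs = NULL,
                         crs_id = "local-metric", nodata = -9999) {
  if (!(road_friction < offroad_friction && offroad_friction < rough_friction))
    stop("friction triple must satisfy road < offroad < rough")
  if (!(urban_share > 0 && urban_share < 1))
    stop("urban_share must lie in (0, 1)")
  if (any(facility_counts < 0)) stop("facility counts must be >= 0")
  stopifnot(all(names(facility_counts) %in% .TIER_CODES),
            all(names(urban_bias) %in% .TIER_CODES),
            all(urban_bias >= 0 & urban_bias <= 1),
            road_count >= 0, n_zones >= 1, n_urban_clusters >= 1,
            total_population > 0, roughness_amplitude >= 0,
            favored_share >= 0, favored_share <= 1)
  if (is.null(service_probs))
    service_probs <- list(
      outpatient     = c(yes = 0.78, no = 0.22, unknown = 0.00),
      inpatient      = c(yes = 0.62, no = 0.38, unknown = 0.00),
      homecare       = c(yes = 0.72, no = 0.28, unknown = 0.00),
      trained_worker = c(yes = 0.91, no = 0.09, unknown = 0.00),
      morphine       = c(yes = 0.63, no = 0.33, unknown = 0.04),
      cost           = c(free = 0.70, free_for_poor = 0.04, paid = 0.22,
                         unknown = 0.04))
  structure(list(seed = as.integer(seed),
                 spec = grid_spec(n_rows, n_cols, cell_size_m,
                                  crs_id = crs_id, nodata = nodata),
                 n_zones = as.integer(n_zones),
                 n_urban_clusters = as.integer(n_urban_clusters),
                 total_population = total_population,
                 urban_share = urban_share,
                 road_count = as.integer(road_count),
                 road_friction = road_friction,
                 offroad_friction = offroad_friction,
                 rough_friction = rough_friction,
                 roughness_amplitude = roughness_amplitude,
                 facility_counts = facility_counts,
                 urban_bias = urban_bias,
                 favored_zone = as.integer(favored_zone),
                 favored_share = favored_share,
                 service_probs = service_probs),
            class = "synth_config")
}

# urban cluster sites, shared between friction (road endpoints) and
# population (kernel centers); kept off the outermost rows/cols
.cluster_sites <- function(cfg) {
  .with_seed(cfg$seed + 1L, {
    sp <- cfg$spec
    margin <- max(1L, min(5L, (min(sp$n_rows, sp$n_cols) - 1L) %/% 4L))
    rows <- sample(seq(1L + margin, sp$n_rows - margin), cfg$n_urban_clusters,
                   replace = cfg$n_urban_clusters > sp$n_rows - 2L * margin)
    cols <- sample(seq(1L + margin, sp$n_cols - margin), cfg$n_urban_clusters,
                   replace = cfg$n_urban_clusters > sp$n_cols - 2L * margin)
    cbind(row = rows, col = cols)
  })
}

#' Generate the zone raster (Voronoi partition)
#'
#' @param cfg a [synth_config()].
#' @return zone [grid_raster()] with codes `1..n_zones`; every cell
#'   labeled by its nearest seeded site (ties to the lowest code).
#' @export
gen_zones <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sp <- cfg$spec
  n_cells <- sp$n_rows * sp$n_cols
  if (cfg$n_zones > n_cells) stop("more zones than grid cells")
  sites <- .with_seed(cfg$seed + 2L, {
    idx <- sample(n_cells, cfg$n_zones)
    cbind(row = (idx - 1L) %% sp$n_rows + 1L,
          col = (idx - 1L) %/% sp$n_rows + 1L)
  })
  rows <- matrix(seq_len(sp$n_rows), sp$n_rows, sp$n_cols)
  cols <- matrix(seq_len(sp$n_cols), sp$n_rows, sp$n_cols, byrow = TRUE)
  best_d <- matrix(Inf, sp$n_rows, sp$n_cols)
  lab <- matrix(0L, sp$n_rows, sp$n_cols)
  for (z in seq_len(cfg$n_zones)) {
    d <- (rows - sites[z, 1L])^2 + (cols - sites[z, 2L])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    lab[upd] <- z
  }
  grid_raster(sp, lab + 0, "zone")
}

# supercover-ish line rasterization between two cells (dense sampling)
.line_cells <- function(r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1)) * 2L + 1L
  t <- seq(0, 1, length.out = n)
  unique(cbind(row = round(r1 + t * (r2 - r1)),
               col = round(c1 + t * (c2 - c1))))
}

# separable box smoothing with edge renormalization
.smooth2d <- function(m, k = 7L) {
  kern <- rep(1, k)
  sm_rows <- function(x) {
    t(apply(x, 1L, function(v) {
      s <- stats::filter(v, kern, sides = 2L)
      n <- stats::filter(rep(1, length(v)), kern, sides = 2L)
      as.numeric(s / n)
    }))
  }
  fill <- function(x) { x[is.na(x)] <- 0; x }
  fill(sm_rows(t(fill(sm_rows(m)))))
}

#' Generate the friction surface
#'
#' Off-road base friction, a smoothed multiplicative roughness field
#' raising some regions toward the rough friction, and `road_count`
#' piecewise-linear corridors between cluster sites set exactly to the
#' road friction.  All values positive; no nodata cells.
#'
#' @param cfg a [synth_config()].
#' @return friction [grid_raster()] in minutes per meter.
#' @export
gen_friction <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sp <- cfg$spec
  f <- .with_seed(cfg$seed + 3L, {
    base <- matrix(cfg$offroad_friction, sp$n_rows, sp$n_cols)
    if (cfg$roughness_amplitude > 0) {
      z <- .smooth2d(matrix(stats::rnorm(sp$n_rows * sp$n_cols),
                            sp$n_rows, sp$n_cols))
      s <- stats::sd(as.vector(z))
      if (s > 0) z <- z / s
      base <- base * exp(cfg$roughness_amplitude * z)
      base <- pmin(pmax(base, cfg$offroad_friction), cfg$rough_friction)
    }
    if (cfg$road_count > 0) {
      sites <- .cluster_sites(cfg)
      n_sites <- nrow(sites)
      for (k in seq_len(cfg$road_count)) {
        if (n_sites >= 2L) {
          pair <- sample(n_sites, 2L)
          a <- sites[pair[1L], ]; b <- sites[pair[2L], ]
        } else {
          a <- c(sample(sp$n_rows, 1L), sample(sp$n_cols, 1L))
          b <- c(sample(sp$n_rows, 1L), sample(sp$n_cols, 1L))
        }
        cells <- .line_cells(a[1L], a[2L], b[1L], b[2L])
        base[cells] <- cfg$road_friction
      }
    }
    base
  })
  grid_raster(sp, f, "friction")
}

#' Generate population and urban mask
#'
#' Gaussian kernels at the cluster sites hold `urban_share` of the total
#' population; an iid lognormal background over the remaining cells holds
#' the rest.  The urban mask is kernel membership (cells within 2.5 sigma
#' of a cluster center), so the rural/urban partition is exact by
#' construction and the urban population share equals `urban_share`
#' exactly.
#'
#' @param cfg a [synth_config()].
#' @return list with `population` and `urban` (mask) [grid_raster()]s.
#' @export
gen_population <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sp <- cfg$spec
  out <- .with_seed(cfg$seed + 4L, {
    sites <- .cluster_sites(cfg)
    rows <- matrix(seq_len(sp$n_rows), sp$n_rows, sp$n_cols)
    cols <- matrix(seq_len(sp$n_cols), sp$n_rows, sp$n_cols, byrow = TRUE)
    sigma <- stats::runif(nrow(sites), 2, 5)
    mass <- stats::rgamma(nrow(sites), shape = 2)
    mass <- mass / sum(mass)
    dens <- matrix(0, sp$n_rows, sp$n_cols)
    urban <- matrix(FALSE, sp$n_rows, sp$n_cols)
    for (i in seq_len(nrow(sites))) {
      d2 <- (rows - sites[i, 1L])^2 + (cols - sites[i, 2L])^2
      member <- d2 <= (2.5 * sigma[i])^2
      urban <- urban | member
      kern <- exp(-d2 / (2 * sigma[i]^2)) * member
      dens <- dens + mass[i] * kern
    }
    pop <- matrix(0, sp$n_rows, sp$n_cols)
    pop[urban] <- dens[urban] / sum(dens[urban]) *
      cfg$urban_share * cfg$total_population
    n_rural <- sum(!urban)
    if (n_rural > 0L) {
      bg <- stats::rlnorm(n_rural, meanlog = 0, sdlog = 1)
      pop[!urban] <- bg / sum(bg) *
        (1 - cfg$urban_share) * cfg$total_population
    }
    list(pop = pop, urban = urban)
  })
  list(population = grid_raster(sp, out$pop, "population"),
       urban = grid_raster(sp, out$urban + 0, "mask"))
}

.sample_cells <- function(cells, n, weights = NULL) {
  if (n <= 0L || !length(cells)) return(integer(0))
  if (length(cells) == 1L) return(rep(cells, n))
  sample(cells, n, replace = TRUE, prob = weights)
}

.draw_tristate <- function(n, p) {
  sample(c("yes", "no", "unknown"), n, replace = TRUE, prob = p)
}

#' Generate tiered facility registries
#'
#' For each tier, an `urban_bias` fraction of facilities lands in urban
#' cells (population-weighted when a population raster is supplied),
#' the remainder uniformly in rural cells.  PCC centres are split first:
#' `favored_share` of them go to the favored zone.  Facility points are
#' jittered uniformly within their cell; service flags are drawn from the
#' configured probabilities.
#'
#' @param cfg a [synth_config()].
#' @param zones zone [grid_raster()] from [gen_zones()].
#' @param urban_mask mask [grid_raster()] from [gen_population()].
#' @param pop optional population [grid_raster()] for weighted urban
#'   placement.
#' @return named list tier -> [facility_set()] (every configured tier,
#'   possibly empty).
#' @export
gen_facilities <- function(cfg, zones, urban_mask, pop = NULL) {
  stopifnot(inherits(cfg, "synth_config"),
            inherits(zones, "grid_raster"),
            inherits(urban_mask, "grid_raster"))
  .require_aligned(zones, urban_mask)
  sp <- cfg$spec
  urb <- urban_mask$values == 1
  if (any(cfg$urban_bias[names(cfg$facility_counts)] > 0,
          na.rm = TRUE) && !any(urb))
    stop("urban mask is empty but a tier has positive urban bias")
  zv <- zones$values
  w <- if (!is.null(pop)) pop$values else NULL

  .with_seed(cfg$seed + 5L, {
    registry <- list()
    for (tier in names(cfg$facility_counts)) {
      n <- as.integer(cfg$facility_counts[[tier]])
      bias <- if (tier %in% names(cfg$urban_bias))
        cfg$urban_bias[[tier]] else 0.5
      if (tier == "PCC" && cfg$favored_share > 0) {
        n_fav <- round(cfg$favored_share * n)
        groups <- list(list(n = n_fav, zone = cfg$favored_zone),
                       list(n = n - n_fav, zone = NA))
      } else {
        groups <- list(list(n = n, zone = NA))
      }
      cells <- integer(0)
      for (g in groups) {
        if (g$n <= 0L) next
        in_zone <- if (is.na(g$zone)) {
          if (tier == "PCC" && cfg$favored_share > 0)
            zv != cfg$favored_zone else rep(TRUE, length(zv))
        } else zv == g$zone
        ucells <- which(in_zone & urb)
        rcells <- which(in_zone & !urb)
        if (!length(ucells)) ucells <- which(in_zone)
        if (!length(rcells)) rcells <- which(in_zone)
        n_u <- round(bias * g$n)
        uw <- if (!is.null(w)) w[ucells] + 1e-9 else NULL
        cells <- c(cells,
                   .sample_cells(ucells, n_u, uw),
                   .sample_cells(rcells, g$n - n_u))
      }
      rr <- (cells - 1L) %% sp$n_rows + 1L
      cc <- (cells - 1L) %/% sp$n_rows + 1L
      ctr <- cell_center(sp, rr, cc)
      jx <- stats::runif(length(cells), -0.499, 0.499) * sp$cell_size_m
      jy <- stats::runif(length(cells), -0.499, 0.499) * sp$cell_size_m
      pr <- cfg$service_probs
      df <- data.frame(
        id = sprintf("%s-%04d", tier, seq_along(cells)),
        x = ctr[, 1L] + jx, y = ctr[, 2L] + jy,
        tier = rep(tier, length(cells)),
        outpatient = .draw_tristate(length(cells), pr$outpatient),
        inpatient = .draw_tristate(length(cells), pr$inpatient),
        homecare = .draw_tristate(length(cells), pr$homecare),
        trained_worker = .draw_tristate(length(cells), pr$trained_worker),
        morphine = .draw_tristate(length(cells), pr$morphine),
        cost_category = sample(names(pr$cost), length(cells),
                               replace = TRUE, prob = pr$cost),
        zone = zv[cells],
        stringsAsFactors = FALSE)
      registry[[tier]] <- facility_set(df, source_label =
                                         paste0("synthetic:", tier))
    }
    registry
  })
}

#' Generate the complete synthetic world in memory
#'
#' @param cfg a [synth_config()] (default configuration if omitted).
#' @return list with `cfg`, `zones`, `friction`, `population`, `urban`,
#'   and `registry` (tier -> [facility_set()]).
#' @export
gen_world <- function(cfg = synth_config()) {
  zones <- gen_zones(cfg)
  friction <- gen_friction(cfg)
  popurb <- gen_population(cfg)
  registry <- gen_facilities(cfg, zones, popurb$urban, popurb$population)
  list(cfg = cfg, zones = zones, friction = friction,
       population = popurb$population, urban = popurb$urban,
       registry = registry)
}

#' Write a facility set as CSV
#' @param fs a [facility_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_facilities_csv <- function(fs, path) {
  stopifnot(inherits(fs, "facility_set"))
  utils::write.csv(fs$facilities, path, row.names = FALSE)
  invisible(path)
}

#' Write the synthetic world to disk in the pipeline's input formats
#'
#' Emits `friction.tif`, `population.tif`, `zones.tif`, `urban.tif`,
#' one `facilities_<tier>.csv` per tier, and `synth_config.txt` echoing
#' the configuration.
#'
#' @param world a [gen_world()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths (the manifest).
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(friction = file.path(dir, "friction.tif"),
             population = file.path(dir, "population.tif"),
             zones = file.path(dir, "zones.tif"),
             urban = file.path(dir, "urban.tif"))
  write_raster(world$friction, paths[["friction"]])
  write_raster(world$population, paths[["population"]])
  write_raster(world$zones, paths[["zones"]])
  write_raster(world$urban, paths[["urban"]])
  for (tier in names(world$registry)) {
    p <- file.path(dir, sprintf("facilities_%s.csv", tier))
    write_facilities_csv(world$registry[[tier]], p)
    paths[[paste0("facilities_", tier)]] <- p
  }
  cfgp <- file.path(dir, "synth_config.txt")
  cfg <- world$cfg
  scalar <- vapply(cfg, function(x) is.atomic(x) && length(x) == 1L,
                   logical(1))
  lines <- c(sprintf("%s = %s", names(cfg$spec),
                     vapply(cfg$spec, format, "")),
             sprintf("%s = %s", names(cfg)[scalar],
                     vapply(cfg[scalar], format, "")),
             sprintf("facility_counts = %s",
                     paste(sprintf("%s:%d", names(cfg$facility_counts),
                                   cfg$facility_counts), collapse = ",")),
             sprintf("urban_bias = %s",
                     paste(sprintf("%s:%g", names(cfg$urban_bias),
                                   cfg$urban_bias), collapse = ",")))
  writeLines(lines, cfgp)
  paths[["config"]] <- cfgp
  paths
}
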
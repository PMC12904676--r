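#' Define a facility-tier scenario
#'
#' A scenario names the union of facility tiers assumed to deliver care.
#' The four conventional scenarios ship as [default_scenarios()]:
#' I = PCC + TH + DH, II = I + CHC, III = II + PHC, IV = III minus PCC
#' (public system only).
#'
#' @param name scenario label.
#' @param tiers nonempty subset of `c("PCC", "TH", "DH", "CHC", "PHC")`.
#' @return object of class `scenario`.
#' @export
scenario <- function(name, tiers) {
  tiers <- unique(as.character(tiers))
  if (!length(tiers) || !all(tiers %in% .TIER_CODES))
    stop("tiers must be a nonempty subset of ",
         paste(.TIER_CODES, collapse = ", "))
  structure(list(name = as.character(name), tiers = tiers),
            class = "scenario")
}

#' The four standard service-delivery scenarios
#' @return named list of [scenario()] objects `I`, `II`, `III`, `IV`.
#' @export
default_scenarios <- function() {
  list(I   = scenario("I",   c("PCC", "TH", "DH")),
       II  = scenario("II",  c("PCC", "TH", "DH", "CHC")),
       III = scenario("III", c("PCC", "TH", "DH", "CHC", "PHC")),
       IV  = scenario("IV",  c("TH", "DH", "CHC", "PHC")))
}

#' Read scenario definitions from a flat key-value config file
#'
#' One scenario per line, `name = tier1+tier2+...`; blank lines and `#`
#' comments ignored.
#'
#' @param path config file path.
#' @return named list of [scenario()] objects.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("scenario config not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad scenario line: ", ln)
    nm <- trimws(kv[1L])
    tiers <- trimws(strsplit(kv[2L], "+", fixed = TRUE)[[1L]])
    out[[nm]] <- scenario(nm, tiers)
  }
  if (!length(out)) stop("no scenarios defined in ", path)
  out
}

#' Assemble a scenario's facility set
#'
#' Unions the registry's tier sets in fixed tier order (PCC, TH, DH, CHC,
#' PHC), so directory centres precede public facilities and win coordinate
#' ties under the greedy [dedupe()] pass applied after the union.  Ids are
#' prefixed with their tier when needed to stay unique across sources.
#'
#' @param scn a [scenario()].
#' @param registry named list mapping tier code to [facility_set()].
#' @param dedupe_tolerance_m cross-source merge radius in meters
#'   (default 100).
#' @return deduplicated [facility_set()] with a `tier` provenance column;
#'   `attr(, "merge_log")` as in [dedupe()].
#' @export
build_scenario_set <- function(scn, registry, dedupe_tolerance_m = 100) {
  stopifnot(inherits(scn, "scenario"), is.list(registry))
  miss <- setdiff(scn$tiers, names(registry))
  if (length(miss)) stop("registry lacks tier(s): ",
                         paste(miss, collapse = ", "))
  ordered <- intersect(.TIER_CODES, scn$tiers)
  parts <- lapply(ordered, function(t) {
    fs <- registry[[t]]
    stopifnot(inherits(fs, "facility_set"))
    f <- fs$facilities
    if (nrow(f)) f$tier <- t
    f
  })
  merged <- do.call(rbind, parts)
  if (anyDuplicated(merged$id))
    merged$id <- paste(merged$tier, merged$id, sep = ":")
  fs <- facility_set(merged, source_label = paste0("scenario:", scn$name))
  dedupe(fs, dedupe_tolerance_m)
}

#' Run and compare facility-network scenarios
#'
#' For each scenario: union + dedupe the tier sets, rasterize to source
#' cells, accumulate travel time, and build the stratified access report.
#' For nested scenarios the pipeline checks the monotonicity invariant
#' (pointwise travel time non-increasing, hence APC non-decreasing, as
#' tiers are added); a violation can only arise from an internal bug and
#' raises an error of class `careatlas_internal_error`.
#'
#' @param scenarios named list of [scenario()] objects, evaluated in order.
#' @param registry named list tier -> [facility_set()].
#' @param friction,pop aligned friction and population rasters.
#' @param zone_raster,urban_mask optional stratification rasters.
#' @param thresholds APC thresholds in minutes.
#' @param dedupe_tolerance_m cross-source merge radius.
#' @param connectivity passed to [accumulate_cost()].
#' @param weighting passed to [build_report()].
#' @return object of class `scenario_comparison`: list with `reports`
#'   (named list of access reports), `travel_times` (named list of
#'   travel-time rasters), `red_zone` (named numeric, population beyond 60
#'   minutes per scenario), `facility_counts`, and `comparison` (long-format
#'   data frame scenario x stratum x metric).
#' @export
run_scenarios <- function(scenarios, registry, friction, pop,
                          zone_raster = NULL, urban_mask = NULL,
                          thresholds = c(30, 60, 120),
                          dedupe_tolerance_m = 100, connectivity = 8L,
                          weighting = "population") {
  stopifnot(length(scenarios) >= 1L)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  .require_aligned(friction, pop)

  reports <- list(); tts <- list(); red <- numeric(0); counts <- integer(0)
  tiersets <- lapply(scenarios, `[[`, "tiers")
  for (nm in names(scenarios)) {
    scn <- scenarios[[nm]]
    fs <- build_scenario_set(scn, registry, dedupe_tolerance_m)
    if (n_facilities(fs) == 0L)
      stop("scenario ", nm, " has no facilities after dedup")
    src <- rasterize_facilities(fs, friction)
    if (nrow(src$cells) == 0L)
      stop("scenario ", nm, " has no placeable facilities on the grid")
    tt <- accumulate_cost(friction, src, connectivity = connectivity)
    reports[[nm]] <- build_report(tt, pop, zone_raster, urban_mask,
                                  thresholds, weighting)
    tts[[nm]] <- tt
    red[nm] <- red_zone_population(tt, pop)
    counts[nm] <- n_facilities(fs)

    # nesting invariant against every earlier scenario whose tier set is a
    # subset of this one
    for (prev in names(tts)) {
      if (prev == nm) next
      if (all(tiersets[[prev]] %in% tiersets[[nm]])) {
        a <- tts[[prev]]$values; b <- tts[[nm]]$values
        ok <- !is.na(a) & !is.na(b)
        if (any(b[ok] > a[ok] + 1e-9))
          stop(structure(class = c("careatlas_internal_error", "error",
                                   "condition"),
                         list(message = paste0(
                           "internal consistency failure: travel time ",
                           "increased from scenario ", prev, " to nested ",
                           "scenario ", nm),
                           call = sys.call(-1))))
      }
    }
  }

  comparison <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    long <- stats::reshape(
      as.data.frame(r), direction = "long",
      varying = setdiff(names(r), c("zone", "settlement", "flagged")),
      v.names = "value",
      times = setdiff(names(r), c("zone", "settlement", "flagged")),
      timevar = "metric")
    data.frame(scenario = nm, zone = long$zone, settlement = long$settlement,
               metric = long$metric, value = long$value,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL

  structure(list(reports = reports, travel_times = tts, red_zone = red,
                 facility_counts = counts, comparison = comparison,
                 thresholds = thresholds),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  for (nm in names(x$reports)) {
    nat <- x$reports[[nm]]
    nat <- nat[nat$zone == "national" & nat$settlement == "total", ]
    cat(sprintf("  %-4s %4d facilities  median %6.1f min  red-zone pop %.0f\n",
                nm, x$facility_counts[[nm]], nat$median_tt,
                x$red_zone[[nm]]))
  }
  invisible(x)
}
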
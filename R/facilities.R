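.TIER_CODES <- c("PCC", "TH", "DH", "CHC", "PHC")
.TRISTATE <- c("yes", "no", "unknown")
.COST_CODES <- c("free", "free_for_poor", "paid", "unknown")
.SERVICE_COLS <- c("outpatient", "inpatient", "homecare", "trained_worker",
                   "morphine")

#' Round half-up at a fixed number of decimals
#'
#' Reporting helper matching the half-up convention of printed tables
#' (base `round()` is round-half-even).
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.as_tristate <- function(x, n) {
  if (is.null(x)) return(rep("unknown", n))
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == "" | x == "na"] <- "unknown"
  x[x %in% c("1", "true", "y")] <- "yes"
  x[x %in% c("0", "false", "n")] <- "no"
  bad <- !(x %in% .TRISTATE)
  if (any(bad)) stop("invalid service flag value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  x
}

#' Construct a facility set
#'
#' The registry container used throughout the pipeline: an ordered data
#' frame of point facilities with a tier code and tri-state service flags
#' (`yes`/`no`/`unknown`; unknown models records missing from the source
#' directory, which is why service percentages can have different
#' denominators).
#'
#' @param df data frame with at least `id`, `x`, `y`, `tier`; optional
#'   service columns `outpatient`, `inpatient`, `homecare`,
#'   `trained_worker`, `morphine` (tri-state), `cost_category`
#'   (`free`/`free_for_poor`/`paid`/`unknown`), `name`, `zone`.
#' @param source_label provenance string.
#' @return object of class `facility_set`.
#' @export
facility_set <- function(df, source_label = "unspecified") {
  stopifnot(is.data.frame(df))
  need <- c("id", "x", "y", "tier")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate facility ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (n && any(!is.finite(df$x) | !is.finite(df$y)))
    stop("non-finite coordinates; reject rows before construction")
  df$tier <- as.character(df$tier)
  if (n && !all(df$tier %in% .TIER_CODES))
    stop("invalid tier code(s): ",
         paste(setdiff(unique(df$tier), .TIER_CODES), collapse = ", "))
  if (is.null(df$name)) df$name <- df$id
  for (sc in .SERVICE_COLS) df[[sc]] <- .as_tristate(df[[sc]], n)
  cc <- df$cost_category
  if (is.null(cc)) cc <- rep("unknown", n)
  cc <- tolower(trimws(as.character(cc)))
  cc[is.na(cc) | cc == "" | cc == "na"] <- "unknown"
  if (n && !all(cc %in% .COST_CODES))
    stop("invalid cost_category value(s): ",
         paste(setdiff(unique(cc), .COST_CODES), collapse = ", "))
  df$cost_category <- cc
  if (is.null(df$zone)) df$zone <- rep(NA_integer_, n)
  keep <- c("id", "name", "x", "y", "tier", .SERVICE_COLS, "cost_category",
            "zone")
  structure(list(facilities = df[, keep], source_label = source_label),
            class = "facility_set")
}

#' @export
print.facility_set <- function(x, ...) {
  cat(sprintf("<facility_set '%s'> %d facilities (%s)\n", x$source_label,
              nrow(x$facilities),
              paste(sprintf("%s:%d", names(table(x$facilities$tier)),
                            table(x$facilities$tier)), collapse = " ")))
  invisible(x)
}

#' Number of facilities in a set
#' @param fs a [facility_set()].
#' @return integer.
#' @export
n_facilities <- function(fs) nrow(fs$facilities)

#' Load a facility registry from CSV
#'
#' Required columns: `id`, plus coordinates as either `x`,`y` (projected
#' meters) or `lon`,`lat` (used verbatim as x,y; project beforehand for
#' metric dedup and gridding).  Rows with unparseable coordinates are
#' rejected into a per-row report attached as attribute `"rejected"`,
#' never silently dropped.
#'
#' @param path CSV path (header required).
#' @param tier tier code applied to rows lacking a `tier` column.
#' @param source_label provenance string (defaults to the file name).
#' @return [facility_set()]; `attr(, "rejected")` is a data frame with
#'   columns `row`, `id`, `reason`.
#' @export
load_facilities <- function(path, tier = NULL, source_label = basename(path)) {
  if (!file.exists(path)) stop("facility file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!("id" %in% names(df))) stop("missing required column(s): id")
  if (all(c("lon", "lat") %in% names(df)) && !all(c("x", "y") %in% names(df))) {
    df$x <- df$lon; df$y <- df$lat
  }
  miss <- setdiff(c("x", "y"), names(df))
  if (length(miss))
    stop("missing required coordinate column(s): x/lon, y/lat")
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- !is.finite(xs) | !is.finite(ys)
  rejected <- data.frame(row = which(bad),
                         id = df$id[bad],
                         reason = rep("unparseable coordinates", sum(bad)),
                         stringsAsFactors = FALSE)
  df <- df[!bad, , drop = FALSE]
  df$x <- xs[!bad]; df$y <- ys[!bad]
  if (is.null(df$tier)) {
    if (is.null(tier)) stop("no tier column and no tier argument given")
    df$tier <- tier
  }
  fs <- facility_set(df, source_label = source_label)
  attr(fs, "rejected") <- rejected
  fs
}

# even-odd ray casting; points on an edge or vertex count as inside
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2L &&
      (poly[1L, 1L] != poly[n, 1L] || poly[1L, 2L] != poly[n, 2L]))
    poly <- rbind(poly, poly[1L, ])          # close the ring
  n <- nrow(poly) - 1L
  scale <- max(abs(poly), abs(px), abs(py), 1)
  eps <- 1e-9 * scale
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    inc <- FALSE; on_edge <- FALSE
    for (i in seq_len(n)) {
      x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
      x2 <- poly[i + 1L, 1L]; y2 <- poly[i + 1L, 2L]
      # on-segment test
      cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cr) <= eps * scale &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) {
        on_edge <- TRUE; break
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inc <- !inc
      }
    }
    inside[k] <- on_edge || inc
  }
  inside
}

.parse_boundary <- function(boundary) {
  if (is.character(boundary) && length(boundary) == 1L) {
    parts <- suppressWarnings(as.numeric(strsplit(boundary, ",")[[1L]]))
    if (length(parts) != 4L || any(!is.finite(parts)))
      stop("bbox string must be 'minx,miny,maxx,maxy'")
    boundary <- parts
  }
  if (is.numeric(boundary) && !is.matrix(boundary) &&
      length(boundary) == 4L) {
    b <- boundary
    if (b[1L] > b[3L] || b[2L] > b[4L])
      stop("invalid bbox: min exceeds max")
    return(cbind(c(b[1L], b[3L], b[3L], b[1L]),
                 c(b[2L], b[2L], b[4L], b[4L])))
  }
  poly <- as.matrix(boundary)
  if (ncol(poly) != 2L || nrow(poly) < 3L || any(!is.finite(poly)))
    stop("boundary must be a bbox or an n x 2 polygon matrix (n >= 3)")
  poly
}

#' Drop facilities outside a boundary
#'
#' @param fs a [facility_set()].
#' @param boundary either `c(minx, miny, maxx, maxy)`, the same as a
#'   comma-separated string, or an `n x 2` polygon matrix (ring closed
#'   automatically).  Points on the boundary are kept.
#' @return filtered [facility_set()]; `attr(, "removed")` holds the number
#'   removed and `attr(, "removed_ids")` their ids.
#' @export
bounds_filter <- function(fs, boundary) {
  stopifnot(inherits(fs, "facility_set"))
  poly <- .parse_boundary(boundary)
  f <- fs$facilities
  keep <- .point_in_polygon(f$x, f$y, poly)
  out <- fs
  out$facilities <- f[keep, , drop = FALSE]
  rownames(out$facilities) <- NULL
  attr(out, "removed") <- sum(!keep)
  attr(out, "removed_ids") <- f$id[!keep]
  out
}

#' Remove coordinate duplicates from a facility set
#'
#' Greedy single pass in input order: a facility is dropped iff it lies
#' within `tolerance_m` (Euclidean, projected meters) of an earlier
#' *retained* facility.  With `tolerance_m = 0` only exact coordinate
#' duplicates are removed.  The pass is idempotent.
#'
#' @param fs a [facility_set()].
#' @param tolerance_m non-negative merge radius in meters.
#' @return deduplicated [facility_set()]; `attr(, "merge_log")` is a data
#'   frame `dropped_id`, `kept_id`, `distance_m`.
#' @export
dedupe <- function(fs, tolerance_m = 0) {
  stopifnot(inherits(fs, "facility_set"))
  if (!is.numeric(tolerance_m) || length(tolerance_m) != 1L ||
      is.na(tolerance_m) || tolerance_m < 0)
    stop("tolerance_m must be a non-negative number")
  f <- fs$facilities
  n <- nrow(f)
  keep <- logical(n)
  kept_idx <- integer(0)
  log_dropped <- character(0); log_kept <- character(0)
  log_dist <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kept_idx)) {
      d2 <- (f$x[kept_idx] - f$x[i])^2 + (f$y[kept_idx] - f$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= tolerance_m^2) {
        log_dropped <- c(log_dropped, f$id[i])
        log_kept <- c(log_kept, f$id[kept_idx[j]])
        log_dist <- c(log_dist, sqrt(d2[j]))
        next
      }
    }
    keep[i] <- TRUE
    kept_idx <- c(kept_idx, i)
  }
  out <- fs
  out$facilities <- f[keep, , drop = FALSE]
  rownames(out$facilities) <- NULL
  attr(out, "merge_log") <- data.frame(dropped_id = log_dropped,
                                       kept_id = log_kept,
                                       distance_m = log_dist,
                                       stringsAsFactors = FALSE)
  out
}

#' Summarize service availability
#'
#' For each tri-state service flag, counts `yes` records against a
#' denominator that is either all records (`"all"`) or only records with a
#' known value (`"known"`); directory-derived tables mix both conventions,
#' so the policy used is recorded in the output.  Cost categories are
#' summarized against records with known cost.
#'
#' @param fs a [facility_set()].
#' @param denominator `"all"` or `"known"` for the tri-state flags.
#' @return data frame `attribute`, `n_yes`, `denominator`, `percentage`
#'   (half-up, one decimal; `NA` when the denominator is 0),
#'   `denominator_policy`.
#' @export
summarize_services <- function(fs, denominator = c("all", "known")) {
  stopifnot(inherits(fs, "facility_set"))
  denominator <- match.arg(denominator)
  f <- fs$facilities
  n <- nrow(f)
  rows <- lapply(.SERVICE_COLS, function(sc) {
    v <- f[[sc]]
    den <- if (denominator == "all") n else sum(v != "unknown")
    num <- sum(v == "yes")
    data.frame(attribute = sc, n_yes = num, denominator = den,
               percentage = if (den > 0)
                 round_half_up(100 * num / den, 1L) else NA_real_,
               denominator_policy = denominator,
               stringsAsFactors = FALSE)
  })
  known_cost <- sum(f$cost_category != "unknown")
  cost_rows <- lapply(c("free", "free_for_poor"), function(cat) {
    num <- sum(f$cost_category == cat)
    data.frame(attribute = paste0("cost_", cat), n_yes = num,
               denominator = known_cost,
               percentage = if (known_cost > 0)
                 round_half_up(100 * num / known_cost, 1L) else NA_real_,
               denominator_policy = "known",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, cost_rows))
}

#' Facility density per ten million population
#'
#' @param n_centres non-negative integer count of centres.
#' @param population positive population.
#' @param digits decimals for half-up rounding (default 1, as density
#'   tables are conventionally printed).
#' @return `1e7 * n_centres / population`, rounded.
#' @export
density_per_10m <- function(n_centres, population, digits = 1L) {
  stopifnot(is.numeric(n_centres), all(n_centres >= 0))
  if (!is.numeric(population) || any(population <= 0))
    stop("population must be positive")
  round_half_up(1e7 * n_centres / population, digits)
}
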
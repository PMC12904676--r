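# Shared fixtures, built in code.  Expensive objects (the default synthetic
# world and its pipeline products) are computed once per test run and
# cached in this environment.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_world <- function() cached("world", gen_world(synth_config(seed = 42L)))

situational_tt <- function() cached("tt", {
  w <- default_world()
  src <- rasterize_facilities(w$registry$PCC, w$friction)
  accumulate_cost(w$friction, src)
})

situational_report <- function() cached("report", {
  w <- default_world()
  build_report(situational_tt(), w$population, w$zones, w$urban)
})

scenario_run <- function() cached("scenarios", {
  w <- default_world()
  run_scenarios(default_scenarios(), w$registry, w$friction, w$population,
                w$zones, w$urban)
})

# small raster helpers -------------------------------------------------

test_spec <- function(nr = 5L, nc = 5L, s = 1000) grid_spec(nr, nc, s)

uniform_friction <- function(nr, nc, f = 0.03, s = 1000,
                             spec = grid_spec(nr, nc, s)) {
  grid_raster(spec, matrix(f, nr, nc), "friction")
}

# log-uniform random friction in [lo, hi], optional nodata patches
random_friction <- function(seed, nr, nc, s = 1000, lo = 0.01, hi = 0.1,
                            p_nodata = 0) {
  set.seed(seed)
  v <- exp(stats::runif(nr * nc, log(lo), log(hi)))
  if (p_nodata > 0) v[stats::runif(nr * nc) < p_nodata] <- NA
  grid_raster(grid_spec(nr, nc, s), matrix(v, nr, nc), "friction")
}

random_sources <- function(seed, friction, k = 2L) {
  set.seed(seed)
  ok <- which(!is.na(friction$values))
  idx <- sample(ok, min(k, length(ok)))
  nr <- friction$spec$n_rows
  data.frame(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

# a facility set encoding the printed directory summary counts:
# 526 centres; outpatient 410 yes; inpatient 324; home care 381; trained
# worker 477; morphine 333 yes / 171 no / 22 unknown; cost free 371,
# free-for-poor 19, paid 118, unknown 18; 234 centres in zone 1
directory_fixture <- function() cached("directory", {
  n <- 526L
  flag <- function(n_yes, n_unknown = 0L) {
    c(rep("yes", n_yes), rep("unknown", n_unknown),
      rep("no", n - n_yes - n_unknown))
  }
  facility_set(data.frame(
    id = sprintf("PCC-%04d", seq_len(n)),
    x = seq_len(n) * 1000, y = rep(0, n), tier = "PCC",
    outpatient = flag(410L),
    inpatient = flag(324L),
    homecare = flag(381L),
    trained_worker = flag(477L),
    morphine = flag(333L, 22L),
    cost_category = c(rep("free", 371L), rep("free_for_poor", 19L),
                      rep("paid", 118L), rep("unknown", 18L)),
    zone = c(rep(1L, 234L), rep(2L, n - 234L)),
    stringsAsFactors = FALSE), source_label = "directory-counts")
})

density_table <- function() {
  utils::read.csv(system.file("extdata", "state_density_2022.csv",
                              package = "careatlas"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}
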
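make_tt <- function(v, spec = grid_spec(nrow(v), ncol(v), 1000)) {
  grid_raster(spec, v, "travel_time")
}
make_pop <- function(v, spec = grid_spec(nrow(v), ncol(v), 1000)) {
  grid_raster(spec, v, "population")
}

test_that("binary_access_mask applies the inclusive cutpoint and propagates NA", {
  tt <- make_tt(matrix(c(0, 30, 30.0001, NA, Inf, 60), 2, 3))
  m <- binary_access_mask(tt, 30)
  expect_equal(as.vector(m$values), c(1, 1, 0, NA, 0, 0))
  all0 <- make_tt(matrix(0, 2, 2))
  expect_true(all(binary_access_mask(all0, 30)$values == 1))
  expect_error(binary_access_mask(all0, 0), "threshold")
  # elementwise oracle on a seeded raster
  set.seed(17)
  v <- matrix(rexp(400, 1 / 60), 20, 20)
  m2 <- binary_access_mask(make_tt(v), 45)
  expect_identical(m2$values, (v <= 45) + 0)
})

test_that("apc does the population-weighted coverage arithmetic", {
  tt <- make_tt(matrix(c(10, 90), 1, 2))
  pop <- make_pop(matrix(c(30, 70), 1, 2))
  expect_equal(apc(tt, pop, 30), 30)
  expect_equal(apc(tt, pop, 120), 100)
  zero <- make_pop(matrix(0, 1, 2))
  expect_warning(res <- apc(tt, zero, 30), "zero population")
  expect_true(is.na(res))
})

test_that("apc equals a flat naive loop on a seeded fixture", {
  set.seed(21)
  n <- 48L
  ttv <- matrix(rexp(n * n, 1 / 50), n, n); ttv[1:5] <- Inf
  popv <- matrix(rlnorm(n * n), n, n)
  strat <- matrix(runif(n * n) < 0.5, n, n)
  tt <- make_tt(ttv); pop <- make_pop(popv)
  for (th in c(30, 60, 120)) {
    num <- 0; den <- 0
    for (r in 1:n) for (c in 1:n) {
      if (!strat[r, c]) next
      den <- den + popv[r, c]
      if (ttv[r, c] <= th) num <- num + popv[r, c]
    }
    expect_equal(apc(tt, pop, th, strat), 100 * num / den,
                 tolerance = 1e-12)
  }
})

test_that("travel_time_summary handles constants and tiny hand cases", {
  tt <- make_tt(matrix(42, 3, 3))
  pop <- make_pop(matrix(1, 3, 3))
  s <- travel_time_summary(tt, pop)
  expect_equal(unname(s[c("median", "q1", "q3", "mean", "sd")]),
               c(42, 42, 42, 42, 0))
  tri <- travel_time_summary(make_tt(matrix(c(10, 20, 90), 1, 3)),
                             make_pop(matrix(1, 1, 3)))
  expect_equal(unname(tri["median"]), 20)
  expect_error(travel_time_summary(tt, make_pop(matrix(0, 3, 3))), "empty")
})

test_that("weighted quantiles match a sort-and-scan oracle", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 40L
    v <- round(rexp(n, 1 / 80), 2)
    w <- round(rlnorm(n), 3)
    tt <- make_tt(matrix(v, 4, 10))
    pop <- make_pop(matrix(w, 4, 10))
    s <- travel_time_summary(tt, pop)
    oracle_q <- function(p) {
      o <- order(v); cw <- cumsum(w[o])
      v[o][which(cw >= p * sum(w))[1]]
    }
    expect_equal(unname(s["q1"]), oracle_q(0.25))
    expect_equal(unname(s["median"]), oracle_q(0.5))
    expect_equal(unname(s["q3"]), oracle_q(0.75))
    expect_equal(unname(s["mean"]), sum(w * v) / sum(w))
  }
})

test_that("unreachable cells sit in the upper tail; pixel weighting differs", {
  v <- matrix(c(1, 2, 3, Inf), 1, 4)
  tt <- make_tt(v)
  pop <- make_pop(matrix(1, 1, 4))
  s <- travel_time_summary(tt, pop)
  expect_equal(unname(s["median"]), 2)   # finite while weight frac < level
  expect_equal(unname(s["q3"]), 3)
  expect_true(is.infinite(s["mean"]))
  sp <- travel_time_summary(tt, weighting = "pixel")
  expect_equal(unname(sp["median"]), 2)
  # population weighting actually weighs
  pop2 <- make_pop(matrix(c(1, 1, 10, 1), 1, 4))
  expect_equal(unname(travel_time_summary(tt, pop2)["median"]), 3)
})

test_that("red_zone_population is the complement of covered population", {
  set.seed(8)
  v <- matrix(rexp(100, 1 / 70), 10, 10); v[1:3] <- Inf
  p <- matrix(rlnorm(100, 3), 10, 10)
  tt <- make_tt(v); pop <- make_pop(p)
  expect_equal(red_zone_population(tt, pop),
               sum(p[v > 60]), tolerance = 1e-12)
  expect_equal(red_zone_population(tt, pop) +
                 sum(p) * apc(tt, pop, 60) / 100,
               sum(p), tolerance = 1e-9)
  expect_equal(red_zone_population(make_tt(matrix(5, 2, 2)),
                                   make_pop(matrix(7, 2, 2))), 0)
})

test_that("classify_heatmap uses upper-inclusive four bands", {
  v <- matrix(c(10, 15, 15.5, 30, 60, 60.0001, Inf, NA), 2, 4)
  cls <- classify_heatmap(make_tt(v))
  expect_equal(as.vector(cls$values), c(1, 1, 2, 2, 3, 4, 4, NA))
  # histogram oracle + partition + class-4/red-zone equivalence
  set.seed(12)
  tvals <- matrix(rexp(900, 1 / 40), 30, 30)
  tt <- make_tt(tvals)
  cls <- classify_heatmap(tt)
  counts <- table(factor(cls$values, levels = 1:4))
  expect_equal(as.vector(counts),
               c(sum(tvals <= 15), sum(tvals > 15 & tvals <= 30),
                 sum(tvals > 30 & tvals <= 60), sum(tvals > 60)))
  expect_equal(sum(counts), 900)
  p <- matrix(rlnorm(900), 30, 30)
  pop <- make_pop(p)
  expect_equal(sum(p[cls$values == 4]), red_zone_population(tt, pop),
               tolerance = 1e-12)
  expect_equal(nrow(heatmap_color_table()), 4L)
})

test_that("build_report shape, trivial saturation, and flagged strata", {
  spec <- grid_spec(6, 6, 1000)
  tt <- grid_raster(spec, matrix(10, 6, 6), "travel_time")
  pop <- grid_raster(spec, matrix(5, 6, 6), "population")
  zones <- grid_raster(spec, matrix(rep(1:2, each = 18), 6, 6), "zone")
  urb <- grid_raster(spec, matrix(c(1, rep(0, 35)), 6, 6), "mask")
  rep <- build_report(tt, pop, zones, urb)
  expect_equal(nrow(rep), (2 + 1) * 3)
  expect_true(all(rep$apc_30 == 100, na.rm = TRUE))
  expect_true(all(rep$apc_120 == 100, na.rm = TRUE))
  # zone 2 has no urban cell -> flagged, not dropped
  z2u <- rep[rep$zone == "2" & rep$settlement == "urban", ]
  expect_true(z2u$flagged)
  expect_true(is.na(z2u$median_tt))
  expect_error(build_report(tt, pop, thresholds = c(60, 30)), "increasing")
})

test_that("report rows equal per-stratum recomposition from the atoms", {
  w <- default_world()
  tt <- situational_tt()
  rep <- situational_report()
  zv <- w$zones$values; uv <- w$urban$values
  pick <- function(zone, settlement) {
    rep[rep$zone == zone & rep$settlement == settlement, ]
  }
  for (zone in c("national", "3", "5")) {
    zmask <- if (zone == "national") matrix(TRUE, 96, 96) else
      zv == as.numeric(zone)
    for (s in c("total", "rural", "urban")) {
      m <- switch(s, total = zmask, rural = zmask & uv == 0,
                  urban = zmask & uv == 1)
      row <- pick(zone, s)
      expect_equal(row$apc_60,
                   round_half_up(apc(tt, w$population, 60, m), 1))
      sm <- travel_time_summary(tt, w$population, m)
      expect_equal(row$median_tt, round_half_up(unname(sm["median"]), 1))
      expect_equal(row$q1_tt, round_half_up(unname(sm["q1"]), 1))
      expect_equal(row$q3_tt, round_half_up(unname(sm["q3"]), 1))
    }
  }
})

test_that("national APC is the population-weighted union of zone APCs", {
  w <- default_world()
  tt <- situational_tt()
  zv <- w$zones$values
  pv <- w$population$values; tv <- tt$values
  for (th in c(30, 60, 120)) {
    num <- den <- 0
    for (z in sort(unique(as.vector(zv)))) {
      m <- zv == z
      num <- num + sum(pv[m & tv <= th])
      den <- den + sum(pv[m])
    }
    expect_equal(apc(tt, w$population, th), 100 * num / den,
                 tolerance = 1e-9)
  }
})
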
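test_that("load_facilities validates, reports rejections, enforces schema", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "f.csv")
  writeLines(c("id,lon,lat,outpatient",
               "a,1000,2000,yes",
               "b,1500,2500,no",
               "c,1800,2800,"), p)
  fs <- load_facilities(p, tier = "PCC")
  expect_s3_class(fs, "facility_set")
  expect_equal(n_facilities(fs), 3L)
  expect_equal(fs$facilities$outpatient, c("yes", "no", "unknown"))
  expect_equal(nrow(attr(fs, "rejected")), 0L)

  writeLines(c("id,lon,lat", "a,1000,2000", "b,1500,", "c,xx,2800"), p)
  fs <- load_facilities(p, tier = "DH")
  expect_equal(n_facilities(fs), 1L)
  rej <- attr(fs, "rejected")
  expect_equal(rej$row, c(2L, 3L))
  expect_equal(rej$id, c("b", "c"))

  writeLines(c("id,lon", "a,1"), p)
  expect_error(load_facilities(p, tier = "PCC"), "coordinate column")
  writeLines(c("id,lon,lat", "a,1,2", "a,3,4"), p)
  expect_error(load_facilities(p, tier = "PCC"), "duplicate")
  writeLines(c("id,lon,lat", "a,1,2"), p)
  expect_error(load_facilities(p, tier = "XX"), "tier")
})

test_that("generator CSVs load back with the configured size", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 11L, n_rows = 32L, n_cols = 32L,
                      facility_counts = c(PCC = 50L))
  world <- gen_world(cfg)
  p <- file.path(dir, "pcc.csv")
  write_facilities_csv(world$registry$PCC, p)
  expect_equal(n_facilities(load_facilities(p)), 50L)
})

test_that("bounds_filter keeps interior and boundary points, counts removals", {
  fs <- facility_set(data.frame(id = letters[1:3],
                                x = c(0.5, 1.0, 2.0),
                                y = c(0.5, 0.5, 2.0), tier = "PCC"))
  kept <- bounds_filter(fs, c(0, 0, 1, 1))
  expect_equal(n_facilities(kept), 2L)   # boundary point kept
  expect_equal(attr(kept, "removed"), 1L)
  expect_equal(attr(kept, "removed_ids"), "c")
  expect_equal(n_facilities(bounds_filter(fs, "0,0,3,3")), 3L)
  expect_error(bounds_filter(fs, c(2, 0, 1, 1)), "invalid bbox")
  expect_error(bounds_filter(fs, matrix(1, 2, 2)), "polygon")
})

test_that("polygon filtering matches a brute-force half-plane oracle", {
  set.seed(3)
  n <- 100L
  fs <- facility_set(data.frame(id = sprintf("p%03d", 1:n),
                                x = runif(n), y = runif(n), tier = "PHC"))
  # half-plane x <= 0.4 realized as a large triangle-free rectangle ring
  poly <- cbind(c(-10, 0.4, 0.4, -10), c(-10, -10, 10, 10))
  kept <- bounds_filter(fs, poly)
  oracle <- sum(fs$facilities$x <= 0.4)
  expect_equal(n_facilities(kept), oracle)
  expect_setequal(kept$facilities$id,
                  fs$facilities$id[fs$facilities$x <= 0.4])
})

test_that("dedupe removes greedy within-tolerance duplicates with a log", {
  fs <- facility_set(data.frame(id = c("a", "b"), x = c(10, 10),
                                y = c(20, 20), tier = "PCC"))
  d <- dedupe(fs, 0)
  expect_equal(n_facilities(d), 1L)
  expect_equal(attr(d, "merge_log")$dropped_id, "b")
  expect_equal(attr(d, "merge_log")$kept_id, "a")

  far <- facility_set(data.frame(id = c("a", "b"), x = c(0, 10000),
                                 y = c(0, 0), tier = "PCC"))
  expect_equal(n_facilities(dedupe(far, 100)), 2L)
  expect_error(dedupe(fs, -1), "non-negative")
})

test_that("dedupe agrees with an O(n^2) greedy oracle and is idempotent", {
  set.seed(5)
  base_x <- runif(20, 0, 50000); base_y <- runif(20, 0, 50000)
  jit <- runif(40, -35, 35)  # |jitter| < 50 m per axis
  df <- data.frame(id = sprintf("f%02d", 1:40),
                   x = c(base_x, base_x + jit[1:20]),
                   y = c(base_y, base_y + jit[21:40]),
                   tier = "CHC")
  fs <- facility_set(df)
  tol <- 100
  # independent oracle: same greedy order, explicit pairwise distances
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    dup <- FALSE
    for (j in kept)
      if (sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2) <= tol) {
        dup <- TRUE; break
      }
    if (!dup) kept <- c(kept, i)
  }
  d <- dedupe(fs, tol)
  expect_equal(n_facilities(d), length(kept))
  expect_equal(d$facilities$id, df$id[kept])
  d2 <- dedupe(d, tol)
  expect_equal(d2$facilities, d$facilities)
  expect_equal(nrow(attr(d2, "merge_log")), 0L)
})

test_that("dedupe with tolerance 0 touches only exact coordinate duplicates", {
  set.seed(9)
  df <- data.frame(id = sprintf("f%02d", 1:30),
                   x = round(runif(30, 0, 10)), y = round(runif(30, 0, 10)),
                   tier = "PHC")
  fs <- facility_set(df)
  d <- dedupe(fs, 0)
  expect_equal(n_facilities(d), nrow(unique(df[, c("x", "y")])))
})

test_that("summarize_services reproduces directory-style percentages", {
  fs <- directory_fixture()
  s_all <- summarize_services(fs, denominator = "all")
  g <- function(s, a) s[s$attribute == a, ]
  expect_equal(g(s_all, "outpatient")$percentage, 77.9)
  expect_equal(g(s_all, "inpatient")$percentage, 61.6)
  expect_equal(g(s_all, "homecare")$percentage, 72.4)
  expect_equal(g(s_all, "trained_worker")$percentage, 90.7)
  s_known <- summarize_services(fs, denominator = "known")
  expect_equal(g(s_known, "morphine")$denominator, 504)
  expect_equal(g(s_known, "morphine")$percentage, 66.1)
  expect_equal(g(s_known, "cost_free")$denominator, 508)
  expect_equal(g(s_known, "cost_free")$percentage, 73.0)
  expect_equal(g(s_known, "cost_free_for_poor")$n_yes, 19)
})

test_that("summarize_services handles the empty set and ignores row order", {
  empty <- facility_set(data.frame(id = character(), x = numeric(),
                                   y = numeric(), tier = character()))
  s <- summarize_services(empty)
  expect_true(all(s$n_yes == 0))
  expect_true(all(is.na(s$percentage)))

  fs <- directory_fixture()
  set.seed(1)
  perm <- fs
  perm$facilities <- fs$facilities[sample(nrow(fs$facilities)), ]
  expect_equal(summarize_services(perm)$n_yes,
               summarize_services(fs)$n_yes)
})

test_that("density_per_10m matches worked examples and scaling laws", {
  expect_equal(density_per_10m(234, 35633000), 65.7)
  expect_equal(density_per_10m(15, 1567000), 95.7)
  expect_equal(density_per_10m(0, 1e6), 0.0)
  expect_error(density_per_10m(3, 0), "positive")
  expect_error(density_per_10m(3, -5), "positive")
  # linear in centres, inversely proportional to population (unrounded scale)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(1:500, 1); p <- runif(1, 1e5, 1e8); k <- sample(2:5, 1)
    expect_equal(density_per_10m(k * n, p, digits = 8),
                 round_half_up(k * 1e7 * n / p, 8))
    expect_equal(density_per_10m(n, k * p, digits = 8),
                 round_half_up(1e7 * n / (k * p), 8))
  }
})
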
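write_fixture_csvs <- function(catch, stations) {
  cpath <- file.path(tempdir(), paste0("catch", as.integer(stats::runif(1, 1, 1e8)), ".csv"))
  spath <- sub("catch", "stations", cpath, fixed = TRUE)
  utils::write.csv(catch, cpath, row.names = FALSE)
  utils::write.csv(stations, spath, row.names = FALSE)
  list(catch = cpath, stations = spath)
}

toy_catch <- function() {
  data.frame(
    station_id = c("S01", "S01", "S02"),
    year = 1990, month = c(5, 6, 5),
    gear = "midwater", age_class = "age0",
    count = c(12, 0, 4), effort = c(6000, 6000, 5500))
}

toy_stations <- function() {
  data.frame(station_id = c("S01", "S02"),
             region = c("central_bay", "san_pablo_bay"),
             lateral_habitat = c("channel", "shoal"))
}

test_that("a well-formed catch table parses to one record per row", {
  p <- write_fixture_csvs(toy_catch(), toy_stations())
  d <- read_catch_table(p$catch, p$stations)
  expect_equal(nrow(d), 3)
  expect_equal(nrow(attr(d, "rejected")), 0)
  expect_true(all(c("region", "lateral_habitat") %in% names(d)))
})

test_that("rows violating preconditions are rejected individually with reasons", {
  bad <- toy_catch()
  bad$effort[2] <- 0
  bad <- rbind(bad, data.frame(station_id = "S99", year = 1990, month = 5,
                               gear = "midwater", age_class = "age0",
                               count = 1, effort = 100))
  bad <- rbind(bad, data.frame(station_id = "S01", year = 1990, month = 13,
                               gear = "midwater", age_class = "age0",
                               count = 1, effort = 100))
  p <- write_fixture_csvs(bad, toy_stations())
  d <- read_catch_table(p$catch, p$stations)
  expect_equal(nrow(d), 2)
  rej <- attr(d, "rejected")
  expect_setequal(rej$reason, c("non-positive effort", "unknown station",
                                "unparseable date"))
})

test_that("column order does not matter and structural defects are errors", {
  shuffled <- toy_catch()[, c(4, 7, 1, 3, 2, 6, 5)]
  p1 <- write_fixture_csvs(toy_catch(), toy_stations())
  p2 <- write_fixture_csvs(shuffled, toy_stations())
  d1 <- read_catch_table(p1$catch, p1$stations)
  d2 <- read_catch_table(p2$catch, p2$stations)
  expect_equal(d1, d2)

  p3 <- write_fixture_csvs(toy_catch()[, -6], toy_stations())
  expect_error(read_catch_table(p3$catch, p3$stations), "count")
  empty <- toy_catch()[0, ]
  p4 <- write_fixture_csvs(empty, toy_stations())
  expect_error(read_catch_table(p4$catch, p4$stations), "empty")
})

test_that("CPUE is count per effort and vectorization matches scalar computation", {
  expect_equal(compute_cpue(12, 6000), 0.002)
  expect_equal(compute_cpue(0, 123), 0)
  expect_error(compute_cpue(1, 0), "positive")
  expect_error(compute_cpue(-1, 10), "non-negative")
  set.seed(2)
  cnt <- rpois(50, 20); eff <- runif(50, 100, 9000)
  expect_equal(compute_cpue(cnt, eff),
               vapply(1:50, function(i) compute_cpue(cnt[i], eff[i]),
                      numeric(1)))
})

test_that("the completeness filter is inclusive at the threshold and idempotent", {
  m <- matrix(NA_real_, 4, 10,
              dimnames = list(paste0("S", 1:4),
                              sprintf("1990-%02d", 1:10)))
  m[1, 1:3] <- 1    # 0.3
  m[2, 1:5] <- 1    # 0.5
  m[3, 1:6] <- 1    # 0.6
  m[4, ] <- 1       # 1.0
  f <- filter_by_completeness(m, 0.5)
  expect_equal(rownames(f), c("S2", "S3", "S4"))
  expect_equal(attr(f, "dropped")$series, "S1")
  f2 <- filter_by_completeness(f, 0.5)
  expect_equal(unname(f2[, ]), unname(f[, ]))
  expect_equal(nrow(filter_by_completeness(m, 1)), 1)
  expect_warning(filter_by_completeness(m[1, , drop = FALSE], 0.5),
                 "no series")
})

test_that("outlier cleaning replaces 2-SD excursions by neighbour interpolation", {
  x <- c(1, 1, 1, 9, 1, 1, 1)
  # whole-series moments with the outlier included: mean 2.1429, sd 3.0237;
  # |9 - mean| = 6.857 >= 2 sd = 6.047, so the spike is replaced by its
  # neighbours' mean
  cl <- clean_series(x)
  expect_equal(as.numeric(cl), rep(1, 7))
  expect_equal(attr(cl, "replacements"), 1L)

  calm <- c(1, 1.2, 0.8, 1.1, 0.9)
  expect_equal(as.numeric(clean_series(calm)), calm)

  # boundary outlier: single available neighbour
  xb <- c(50, 1, 1.2, 0.8, 1, 1.1)
  expect_equal(as.numeric(clean_series(xb))[1], 1)

  expect_warning(clean_series(c(1, 2, NA, NA, NA)), "fewer than 3")
})

test_that("cleaning leaves missing cells missing", {
  x <- c(1, NA, 1, 1, 30, 1, 1, NA, 1, 1)
  cl <- clean_series(x)
  expect_equal(which(is.na(cl)), c(2, 8))
  expect_equal(as.numeric(cl[5]), 1)
  expect_equal(attr(cl, "replacements"), 1L)
})

test_that("annual aggregation averages the window and enforces the minimum-month rule", {
  m <- matrix(NA_real_, 1, 24,
              dimnames = list("S1", sprintf("%d-%02d", rep(1990:1991, each = 12), 1:12)))
  m[1, 5:10] <- c(2, 2, 2, 4, 4, 4)       # May-Oct 1990
  m[1, 12 + 5] <- 7                        # only May in 1991: below half
  a <- aggregate_annual(m, 5:10)
  expect_equal(unname(a[1, "1990"]), 3)
  expect_true(is.na(a[1, "1991"]))
  expect_error(aggregate_annual(m, integer(0)), "empty")
})

test_that("annual values stay within the window range and respect relabeling", {
  set.seed(9)
  m <- matrix(runif(36, 0, 5), 3, 12,
              dimnames = list(c("A", "B", "C"), sprintf("1990-%02d", 1:12)))
  a <- aggregate_annual(m, 5:10)
  for (i in 1:3) {
    w <- m[i, 5:10]
    expect_gte(a[i, 1], min(w)); expect_lte(a[i, 1], max(w))
  }
  perm <- c(3, 1, 2)
  expect_equal(unname(aggregate_annual(m[perm, ], 5:10)),
               unname(a[perm, , drop = FALSE]))
})

test_that("daily flow aggregated via months equals the mean of monthly means", {
  set.seed(4)
  days <- seq(as.Date("1990-01-01"), as.Date("1990-12-31"), by = "day")
  daily <- data.frame(date = as.character(days),
                      outflow = exp(rnorm(length(days), 10, 0.3)))
  f <- tempfile(fileext = ".csv"); utils::write.csv(daily, f, row.names = FALSE)
  monthly <- read_flow(f)
  ann <- annual_flow(monthly, months = 1:6)
  by_month <- tapply(daily$outflow, format(days, "%m"), mean)[1:6]
  expect_equal(unname(ann["1990"]), mean(by_month))
})

test_that("the log offset is half the smallest positive CPUE per series", {
  m <- matrix(c(0, 0.2, 0.4, 1), 1, 4,
              dimnames = list("S1", sprintf("1990-%02d", 1:4)))
  lg <- log_cpue_matrix(m)
  expect_equal(unname(attr(lg, "delta")), 0.1)
  expect_equal(unname(lg[1, 1]), log(0.1))
})

test_that("flow standardization is a z-score of log flow", {
  x <- c(1e4, 3e4, 9e4, 2e4)
  s <- standardize_flow(x)
  expect_equal(mean(s), 0)
  expect_equal(sd(s), 1)
  expect_equal(order(s), order(x))
  expect_error(standardize_flow(rep(5, 4)), "constant")
  expect_error(standardize_flow(c(-1, 2, 3)), "positive")
})
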
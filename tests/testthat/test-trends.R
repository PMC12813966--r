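test_that("Theil-Sen matches hand-computed and brute-force pairwise medians", {
  expect_equal(theil_sen(c(1, 2, 3), t = c(0, 1, 2))$slope, 1)
  # pairwise slopes of (0,3,1,4): {3, 0.5, 4/3, -2, 0.5, 3}, median 0.9167
  expect_equal(theil_sen(c(0, 3, 1, 4), t = 0:3)$slope, (0.5 + 4 / 3) / 2)
  expect_equal(theil_sen(rep(2, 6))$slope, 0)
  expect_error(theil_sen(c(1, NA, 2)), "at least 3")

  for (s in 1:60) {
    set.seed(s)
    n <- sample(4:15, 1)
    y <- rnorm(n) + 0.2 * seq_len(n)
    y[sample(n, size = sample(0:2, 1))] <- NA
    if (sum(!is.na(y)) < 3) next
    expect_equal(theil_sen(y)$slope, brute_theil_sen(y))
  }
})

test_that("Theil-Sen is insensitive to the magnitude of a single gross outlier", {
  set.seed(10)
  y <- 0.5 * (1:9) + rnorm(9, 0, 0.1)
  y5a <- y; y5a[5] <- 100
  y5b <- y; y5b[5] <- 1e6
  expect_equal(theil_sen(y5a)$slope, theil_sen(y5b)$slope)
})

test_that("the Mann-Kendall p-value flags monotone series and not noise", {
  set.seed(3)
  expect_lt(theil_sen(1:20 + rnorm(20, 0, 0.5))$p_value, 0.01)
  expect_gt(theil_sen(rnorm(20))$p_value, 0.05)
})

test_that("CV is 100 sd / |mean| with the documented edge cases", {
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  expect_equal(cv_percent(rep(4, 7)), 0)
  expect_warning(v <- cv_percent(c(-1, 1)), "zero mean")
  expect_true(is.na(v))
})

test_that("trend/CV regressions reduce to the pooled line for homogeneous groups", {
  df <- data.frame(series_id = paste0("s", 1:8),
                   slope = rep(c(-0.1, 0.2), 4),
                   p_value = 0.5,
                   cv_percent = rep(c(30, 60), 4),
                   n = 10,
                   group = rep(c("a", "b"), each = 4))
  r <- suppressWarnings(trend_cv_regression(df))  # exact-fit fixture
  expect_equal(r$groups$slope, rep(r$pooled$slope, 2))
  expect_equal(r$shares[["negative"]], 0.5)

  # closed-form check on a constructed two-group set
  set.seed(1)
  df2 <- data.frame(series_id = paste0("s", 1:10),
                    slope = rnorm(10), p_value = 0.5,
                    cv_percent = rnorm(10, 50, 10), n = 10,
                    group = rep(c("a", "b"), each = 5))
  r2 <- trend_cv_regression(df2)
  for (g in c("a", "b")) {
    d <- df2[df2$group == g, ]
    b <- cov(d$slope, d$cv_percent) / var(d$slope)
    expect_equal(r2$groups$slope[r2$groups$group == g], b)
  }
  df2$group[df2$group == "b"] <- c("b", "b", "c", "c", "c")[1:5]
  r3 <- trend_cv_regression(df2)
  expect_true("b" %in% r3$omitted)
})

test_that("the fall-index aggregation is a weighted September-December sum", {
  one <- expand.grid(year = 2000, month = 9:12, region = "r1")
  one$value <- 3
  expect_equal(fmwt_style_index(one)$index, 12)

  two <- expand.grid(year = 2000, month = 9:12, region = c("r1", "r2"))
  two$value <- 1
  w <- c(r1 = 2, r2 = 1)
  expect_equal(fmwt_style_index(two, w)$index, 12)
  expect_equal(fmwt_style_index(two, 2 * w)$index, 24)

  partial <- two[two$month != 12 | two$region != "r1", ]
  partial <- partial[!(partial$month == 12), ]
  expect_true(fmwt_style_index(partial, w)$partial)
})

test_that("period regressions reproduce closed-form OLS and flag short periods", {
  idx <- data.frame(year = c(1981:1985, 1990:1994, 2005:2009),
                    index = NA)
  set.seed(6)
  flow <- setNames(exp(rnorm(length(idx$year), 10, 0.4)), idx$year)
  idx$index <- 1e-3 * as.numeric(flow)^1.2 * exp(rnorm(nrow(idx), 0, 0.2))
  pr <- period_regressions(idx, flow)
  expect_setequal(pr$period, c("pre_clam", "pre_pod", "post_pod"))
  for (p in pr$period) {
    yrs <- switch(p, pre_clam = 1981:1985, pre_pod = 1990:1994,
                  post_pod = 2005:2009)
    x <- log10(as.numeric(flow[as.character(yrs)]))
    y <- log10(idx$index[idx$year %in% yrs])
    b <- cov(x, y) / var(x)
    expect_equal(pr$slope[pr$period == p], b, tolerance = 1e-10)
    expect_equal(pr$r_squared[pr$period == p], cor(x, y)^2, tolerance = 1e-10)
  }
  expect_true(all(pr$r_squared >= 0 & pr$r_squared <= 1))

  # perfectly collinear toy data
  toy <- data.frame(year = 1981:1986, index = 10^(1:6))
  toyflow <- setNames(10^(3 + (1:6) / 2), 1981:1986)
  prt <- suppressWarnings(period_regressions(toy, toyflow,
                                             breaks = c(1990, 2000)))
  expect_equal(prt$r_squared[1], 1)
  expect_equal(prt$slope[1], 2)
  expect_equal(attr(prt, "omitted"), c("period2", "period3"))

  # no breaks inside the range: equals one whole-range OLS
  pr_all <- period_regressions(idx, flow, breaks = c(1800, 1801))
  xx <- log10(as.numeric(flow)); yy <- log10(idx$index)
  expect_equal(pr_all$slope[pr_all$n == 15], cov(xx, yy) / var(xx))
})
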
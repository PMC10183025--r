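test_that("daily_series validates its invariants", {
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = 5)
  expect_s3_class(daily_series(d, 1:5), "daily_series")
  expect_error(daily_series(d[c(1, 2, 4, 5, 3)], 1:5), "consecutive")
  expect_error(daily_series(d, 1:4), "length")
  expect_error(daily_series(d, c(1, 2, Inf, 4, 5)), "infinite")
  expect_silent(daily_series(d, c(1, NA, 3, NA, 5)))
})

test_that("aggregate_rolling matches hand-computed windows", {
  s <- make_series(1:5)
  expect_equal(aggregate_rolling(s, 3)$values, c(NA, NA, 6, 9, 12))
  expect_equal(aggregate_rolling(s, 1)$values, s$values)
  const <- make_series(rep(2.5, 100))
  agg <- aggregate_rolling(const, 30)
  expect_true(all(is.na(agg$values[1:29])))
  expect_equal(agg$values[30:100], rep(75, 71))
  expect_error(aggregate_rolling(s, 0), "k")
  expect_error(aggregate_rolling(s, -3), "k")
})

test_that("rolling windows respect the completeness threshold", {
  v <- rep(1, 30)
  v[c(5, 6)] <- NA # window ending day 10 has 8/10 < 90%
  s <- make_series(v)
  agg <- aggregate_rolling(s, 10)
  expect_true(is.na(agg$values[10]))
  # one missing of ten (90% exactly) passes and is rescaled to k days
  v2 <- rep(1, 30); v2[5] <- NA
  agg2 <- aggregate_rolling(make_series(v2), 10)
  expect_equal(agg2$values[10], 10)
  # threshold is configurable
  agg3 <- aggregate_rolling(s, 10, min_frac = 0.5)
  expect_equal(agg3$values[10], 10)
})

test_that("aggregation is linear where both inputs are present", {
  set.seed(101)
  x <- make_series(rnorm(200))
  y <- make_series(rnorm(200))
  z <- make_series(2 * x$values - 3 * y$values)
  ax <- aggregate_rolling(x, 7)$values
  ay <- aggregate_rolling(y, 7)$values
  az <- aggregate_rolling(z, 7)$values
  ok <- !is.na(az)
  expect_equal(az[ok], (2 * ax - 3 * ay)[ok], tolerance = 1e-12)
})

test_that("default aggregation periods enumerate the published scheme", {
  p <- default_aggregation_periods()
  expect_identical(p[1], 5L)
  expect_identical(p[length(p)], 720L)
  expect_length(p, 109L)
  expect_true(all(diff(p) > 0))
  expect_true(all(p[p <= 365] %% 5 == 0))
  expect_true(all(diff(p[p >= 370]) == 10))
})

test_that("climatological samples collect one value per usable year", {
  dates <- seq(as.Date("1950-01-01"), as.Date("2021-12-31"), by = "day")
  set.seed(7)
  vals <- rnorm(length(dates))
  s <- daily_series(dates, vals)
  cs <- climatological_sample(s, 7, 1)
  expect_identical(cs$n, 72L)
  expect_identical(cs$years, 1950:2021)
  # knock out one whole year
  v2 <- vals
  v2[format(dates, "%Y") == "1960"] <- NA
  cs2 <- climatological_sample(daily_series(dates, v2), 7, 1)
  expect_identical(cs2$n, 71L)
  expect_false(1960L %in% cs2$years)
})

test_that("Feb 29 pools with Feb 28", {
  dates <- seq(as.Date("1950-01-01"), as.Date("2021-12-31"), by = "day")
  s <- daily_series(dates, seq_along(dates))
  n_leap <- sum(sapply(1950:2021, function(y) {
    (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  }))
  expect_identical(n_leap, 18L)
  cs29 <- climatological_sample(s, 2, 29)
  expect_identical(cs29$n, 72L + n_leap)
  cs28 <- climatological_sample(s, 2, 28)
  expect_identical(cs28$values, cs29$values)
  # no missing marker ever inside a sample
  expect_false(anyNA(cs29$values))
})

test_that("insufficient climatology raises an informative error", {
  s <- make_years_series(10, function(n) rnorm(n))
  expect_error(climatological_sample(s, 7, 1), "at least 30")
  expect_silent(climatological_sample(s, 7, 1, min_sample_size = 5))
})
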
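test_that("nrmse normalizes RMSE by the observation spread", {
  set.seed(51)
  obs <- rnorm(50, 10, 3)
  expect_equal(nrmse(obs, obs), 0)
  expect_equal(nrmse(obs, obs + sd(obs)), 1)
  expect_error(nrmse(obs[1:3], obs), "equal length")
  expect_error(nrmse(obs[1], obs[1]), "pairs")
  expect_error(nrmse(c(1, NA), c(2, 3)), "pairs")
  expect_error(nrmse(rep(2, 10), rnorm(10)), "zero")
  # alternative normalizations
  expect_equal(nrmse(obs, obs + sd(obs), "mean"), sd(obs) / mean(obs))
  expect_equal(nrmse(obs, obs + sd(obs), "range"), sd(obs) / diff(range(obs)))
})

test_that("r_squared is the squared Pearson correlation", {
  set.seed(52)
  obs <- rnorm(100)
  expect_equal(r_squared(obs, 2 * obs + 3), 1)
  expect_equal(r_squared(obs, -obs), 1) # sign-blind
  big <- rnorm(1e4)
  expect_lt(r_squared(big, rnorm(1e4)), 0.01)
  expect_error(r_squared(obs, rep(1, 100)), "zero variance")
  expect_error(r_squared(obs[1:2], obs[1:2]), "pairs")
})

test_that("standardize centers and scales, ignoring missing values", {
  set.seed(53)
  x <- c(rnorm(50, 5, 2), NA, NA)
  z <- standardize(x)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(is.na(z[51:52])))
  expect_equal(standardize(3 * x + 7), z, tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "zero variance")
})

test_that("doy_zscore removes any deterministic seasonal cycle", {
  dates <- seq(as.Date("1990-01-01"), as.Date("1999-12-31"), by = "day")
  # a cycle keyed to the calendar day itself (Feb 29 sharing Feb 28's
  # value) so it repeats identically every year despite leap years
  md <- format(dates, "%m-%d")
  md2 <- ifelse(md == "02-29", "02-28", md)
  slot <- match(md2, sort(unique(md2)))
  seasonal <- 10 * sin(2 * pi * slot / 365)
  # identical cycle every year: zero within-day variance everywhere
  expect_warning(z0 <- doy_zscore(daily_series(dates, seasonal)),
                 "zero cross-year variance")
  expect_true(all(is.na(z0$values)))
  # cycle + noise: per-day mean 0 by construction
  set.seed(54)
  noise <- rnorm(length(dates))
  z1 <- doy_zscore(daily_series(dates, seasonal + noise))
  agg_mean <- tapply(z1$values, md2, mean, na.rm = TRUE)
  expect_lt(max(abs(agg_mean), na.rm = TRUE), 1e-10)
  # adding another deterministic cycle changes nothing
  z2 <- doy_zscore(daily_series(dates, seasonal + noise + 5 * cos(2 * pi * slot / 365)))
  expect_equal(z2$values, z1$values, tolerance = 1e-10)
})

test_that("rolling correlation fields behave at the identities", {
  dates <- seq(as.Date("1990-01-01"), as.Date("2009-12-31"), by = "day")
  set.seed(55)
  v <- rnorm(length(dates))
  resp <- daily_series(dates, v)
  tab <- sdi_table_skeleton(dates, "SPI", periods = c(5L, 30L))
  tab$SPI_5 <- v                    # identical to the response
  tab$SPI_30 <- rnorm(length(dates)) # independent noise
  fld <- rolling_correlation_field(resp, tab, window_days = 14)
  expect_equal(unname(fld[, "SPI_5"]), rep(1, nrow(fld)), tolerance = 1e-12)
  expect_lt(abs(mean(fld[, "SPI_30"])), 0.05)
  expect_true(all(abs(fld) <= 1))
  # season filter: rows span May-September calendar days only
  expect_equal(nrow(fld), 31 + 30 + 31 + 31 + 30)
  expect_identical(rownames(fld)[1], "05-01")
  # too-small windows refuse; sparse windows go missing
  expect_error(rolling_correlation_field(resp, tab, window_days = 2), ">= 3")
  sparse <- daily_series(dates, ifelse(seq_along(dates) %% 1000 == 0, v, NA))
  fld2 <- rolling_correlation_field(sparse, tab, window_days = 3)
  expect_true(anyNA(fld2))
})
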
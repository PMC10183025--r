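test_that("the site generator is deterministic and internally consistent", {
  cfg <- synthetic_site_config(years = 6, seed = 99)
  a <- generate_site(cfg)
  b <- generate_site(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_site(synthetic_site_config(years = 6,
                                                                seed = 100))))
  expect_equal(nrow(a), as.integer(sum(sapply(1950:1955, function(y)
    365 + ((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0)))))
  expect_true(all(a$TN <= a$TG & a$TG <= a$TX))
  expect_true(all(a$PREC >= 0))
  expect_true(all(a$SM_top >= 0 & a$SM_top <= 1))
  expect_true(all(a$SM_full >= 0 & a$SM_full <= 1))
  expect_true(all(a$PET >= 0 & a$RG >= 0))
  expect_equal(a$AET, a$PET * a$SM_full)
  expect_named(a, c("Date", "Doy", "lon", "lat", "PREC", "TG", "TN", "TX",
                    "PET", "RG", "AET", "SM_top", "SM_full"))
})

test_that("generator statistics match their configured targets", {
  cfg <- synthetic_site_config(years = 72, seed = 7)
  tab <- generate_site(cfg)
  nd <- nrow(tab)
  # dry-day fraction within the binomial 99% CI around the mean
  # occurrence complement (seasonal modulation averages out)
  p_dry <- 1 - cfg$precip_occ_mean
  half <- qnorm(0.995) * sqrt(p_dry * (1 - p_dry) / nd)
  expect_lt(abs(mean(tab$PREC == 0) - p_dry), half + 0.01)
  # seasonal temperature amplitude recovered from monthly means
  mo <- as.integer(format(tab$Date, "%m"))
  mm <- tapply(tab$TG, mo, mean)
  expect_equal(unname(diff(range(mm))), 2 * cfg$temp_amp, tolerance = 0.1)
  # soil moisture persists (lag-1 autocorrelation high)
  expect_gt(cor(tab$SM_top[-1], tab$SM_top[-nd]), 0.95)
})

test_that("known-distribution draws agree with their exact oracle", {
  g <- generate_known_distribution(shape = 2, scale = 5, q = 0.3,
                                   years = 40, seed = 8)
  expect_identical(g$series$values,
                   generate_known_distribution(years = 40, seed = 8)$series$values)
  # oracle cdf basics
  med_pos <- qgamma(0.5, 2, scale = 5)
  g0 <- generate_known_distribution(q = 0, years = 40, seed = 8)
  expect_equal(g0$cdf(med_pos), 0.5)
  expect_equal(g$cdf(0), 0.3)
  # k-day-sum oracle agrees with plain Gamma when q = 0
  xs <- c(5, 20, 60)
  expect_equal(g0$cdf_sum(xs, 4), pgamma(xs, 8, scale = 5), tolerance = 1e-12)
  # and with Monte Carlo for the zero-inflated case
  set.seed(9)
  sums <- colSums(matrix(rbinom(30 * 2e4, 1, 0.7) *
                           rgamma(30 * 2e4, 2, scale = 5), nrow = 30))
  for (x in c(100, 200, 300)) {
    expect_equal(g$cdf_sum(x, 30), mean(sums <= x), tolerance = 0.02)
  }
  # empirical zero fraction within the binomial CI of q
  nd <- length(g$series$values)
  half <- qnorm(0.995) * sqrt(0.3 * 0.7 / nd)
  expect_lt(abs(mean(g$series$values == 0) - 0.3), half)
  expect_error(generate_known_distribution(q = 1), "degenerate")
})

test_that("generated tables survive the io round trip and the pipeline", {
  cfg <- synthetic_site_config(years = 35, seed = 13, latitude = 61.8)
  tab <- generate_site(cfg)
  path <- tempfile(fileext = ".csv")
  write_site_input(tab, path)
  site <- read_site_input(path)
  expect_equal(site$prec$values, round(tab$PREC, 4), tolerance = 1e-9)
  spi <- compute_spi(site$prec, periods = 30L)
  expect_gt(sum(!is.na(spi$SPI_30)), 12000)
  expect_lt(abs(mean(spi$SPI_30, na.rm = TRUE)), 0.1)
})
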
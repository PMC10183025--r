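test_that("the normal-score transform reproduces its anchor points", {
  expect_lt(abs(probability_to_sdi(0.5)), 1e-4)
  expect_equal(probability_to_sdi(0.023), -2.00, tolerance = 0.01)
  expect_equal(probability_to_sdi(0.977), 2.00, tolerance = 0.01)
  expect_equal(probability_to_sdi(0.159), -1.00, tolerance = 0.01)
  expect_error(probability_to_sdi(0), "strictly")
  expect_error(probability_to_sdi(1), "strictly")
  expect_error(probability_to_sdi(-0.2), "strictly")
})

test_that("the transform is antisymmetric and accurate against qnorm", {
  f <- seq(0.001, 0.999, by = 0.001)
  f <- f[abs(f - 0.5) > 1e-9] # at F = 0.5 the two branches meet within 3e-6
  expect_equal(probability_to_sdi(1 - f), -probability_to_sdi(f),
               tolerance = 1e-12)
  fg <- seq(0.001, 0.999, by = 1e-5)
  expect_lt(max(abs(probability_to_sdi(fg) - qnorm(fg))), 1e-3)
  # sign convention: dry (low F) is negative
  expect_true(all(probability_to_sdi(f[f < 0.5]) < 0))
  expect_true(all(probability_to_sdi(f[f > 0.5]) > 0))
})

test_that("probability clipping bounds the index for a finite sample", {
  expect_equal(clip_probability(0, 72), 1 / 146)
  expect_equal(clip_probability(1, 72), 1 - 1 / 146)
  expect_equal(clip_probability(0.4, 72), 0.4)
  expect_equal(probability_to_sdi(clip_probability(0, 72)), -2.46,
               tolerance = 0.01)
})

test_that("the zero-inflated mixture assigns the dry mass correctly", {
  set.seed(21)
  pos <- rgamma(60, 2, scale = 5)
  # q = 0 collapses exactly onto the plain kernel cdf
  m0 <- zero_inflated_model(pos)
  k0 <- kde_model(pos, bandwidth = m0$positive_model$bandwidth)
  xs <- c(0.5, 2, 10, 30)
  expect_equal(zero_inflated_cdf(m0, xs), kde_cdf(k0, xs))
  # q = 0.5 with positive part symmetric about 10
  sym <- 10 + c(-seq(0.5, 4.5, by = 0.5), seq(0.5, 4.5, by = 0.5))
  m5 <- zero_inflated_model(c(rep(0, length(sym)), sym))
  expect_equal(m5$q, 0.5)
  expect_equal(zero_inflated_cdf(m5, 10), 0.75, tolerance = 1e-6)
  # all dry days share F(0) = q
  m3 <- zero_inflated_model(c(rep(0, 30), pos))
  expect_equal(zero_inflated_cdf(m3, 0), m3$q)
  # F(x) >= q everywhere and nondecreasing
  grid <- seq(0, 60, by = 0.5)
  fg <- zero_inflated_cdf(m3, grid)
  expect_true(all(fg >= m3$q))
  expect_true(all(diff(fg) >= 0))
  expect_error(zero_inflated_model(rep(0, 40)), "degenerate")
  expect_error(zero_inflated_model(c(-1, 2)), ">= 0")
  expect_error(zero_inflated_cdf(m3, -2), ">= 0")
})

test_that("sdi_from_sample standardizes targets against the climatology", {
  set.seed(22)
  sym <- rnorm(72, mean = 50, sd = 8)
  sym <- c(sym, 100 - sym) # exactly symmetric about 50
  expect_equal(sdi_from_sample(sym, 50, "water_balance"), 0, tolerance = 0.02)
  # far-out targets hit the clip bound, never infinity
  x <- rgamma(72, 2, scale = 5)
  lo <- sdi_from_sample(x, -500, "water_balance")
  expect_equal(lo, probability_to_sdi(1 / 146), tolerance = 1e-9)
  expect_equal(lo, -2.46, tolerance = 0.01)
  # monotone in the target value
  targ <- seq(min(x), max(x), length.out = 25)
  out <- sdi_from_sample(x, targ, "precipitation")
  expect_true(all(diff(out) >= 0))
  expect_error(sdi_from_sample(x[1:10], 3, "precipitation"), "below minimum")
})

test_that("scores from iid climatologies are approximately standard normal", {
  set.seed(23)
  stats <- t(replicate(40, {
    x <- rgamma(72, shape = 2, scale = 5)
    s <- sdi_from_sample(x, x, "water_balance")
    c(mean(s), sd(s))
  }))
  expect_lt(abs(mean(stats[, 1])), 0.15)
  expect_gt(mean(stats[, 2]), 0.8)
  expect_lt(mean(stats[, 2]), 1.2)
})
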
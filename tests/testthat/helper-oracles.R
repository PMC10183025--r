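# Independent oracles used by the dual-route checks. These deliberately
# avoid the package's own code paths.

# Brute-force CV criterion: trapezoid integration of the squared kernel
# density plus a directly summed leave-one-out term.
cv_numeric_oracle <- function(sample, h, grid_n = 20001L) {
  n <- length(sample)
  lo <- min(sample) - 8 * h
  hi <- max(sample) + 8 * h
  xs <- seq(lo, hi, length.out = grid_n)
  fhat <- sapply(xs, function(x) mean(dnorm((x - sample) / h)) / h)
  dx <- xs[2] - xs[1]
  int_f2 <- sum((fhat[-1]^2 + fhat[-grid_n]^2) / 2) * dx
  loo <- sum(sapply(seq_len(n), function(i) {
    mean(dnorm((sample[i] - sample[-i]) / h)) / h
  }))
  int_f2 - (2 / n) * loo
}

# FAO-56-style daily extraterrestrial radiation, written independently
# (different structure and intermediate variables) with the same
# 365.25-day angle convention.
fao56_ra_oracle <- function(lat_deg, doy) {
  phi <- lat_deg / 180 * pi
  b <- 2 * pi * doy / 365.25
  decl <- 0.409 * sin(b - 1.39)
  dist <- 1 + 0.033 * cos(b)
  x <- -tan(phi) * tan(decl)
  ws <- acos(max(-1, min(1, x)))
  gsc <- 0.0820 # MJ m-2 min-1
  ra <- (1440 / pi) * gsc * dist *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  max(ra, 0)
}

# Exact SDI under a k-day sum of iid zero-inflated Gamma variables:
# mixture over the Binomial number of wet days.
mixture_gamma_sdi_oracle <- function(x, k, shape, scale, q) {
  m <- 0:k
  w <- dbinom(m, k, 1 - q)
  f <- vapply(x, function(xx) {
    comp <- ifelse(m == 0, as.numeric(xx >= 0),
                   pgamma(xx, shape = shape * m, scale = scale))
    sum(w * comp)
  }, numeric(1))
  qnorm(f)
}

# Daily series over whole calendar years.
make_series <- function(values, start = "2000-01-01", units = "") {
  daily_series(seq(as.Date(start), by = "day", length.out = length(values)),
               values, units = units)
}

# n whole calendar years of values from a generator function(nd),
# starting at start_year.
make_years_series <- function(n_years, gen, start_year = 1950, units = "") {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  daily_series(dates, gen(length(dates)), units = units)
}
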
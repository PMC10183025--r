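#' Configuration for the synthetic site generator
#'
#' Defaults emulate the statistical structure of a mid-latitude European
#' site over the canonical 1950-2021 record: a zero-inflated, seasonally
#' modulated daily precipitation process; a seasonal temperature cycle
#' with persistent (AR(1)) anomalies and a guaranteed `TN <= TG <= TX`
#' ordering; latitude-derived radiation and Hargreaves-Samani PET; and
#' two leaky-bucket soil-moisture stores (top ~30 cm, full ~200 cm)
#' bounded in `[0, 1]` with realistic persistence.
#'
#' @param years number of calendar years (default 72, i.e. 1950-2021).
#' @param start_year first year (default 1950).
#' @param latitude site latitude in decimal degrees (default 50).
#' @param longitude site longitude in decimal degrees (default 10).
#' @param precip_occ_mean,precip_occ_amp mean wet-day probability and
#'   its seasonal amplitude (wetter winters for the defaults).
#' @param gamma_shape wet-day precipitation Gamma shape.
#' @param gamma_scale_mean,gamma_scale_amp mean and seasonal amplitude
#'   of the wet-day Gamma scale (mm); larger summer scale mimics
#'   convective events.
#' @param temp_mean,temp_amp annual mean temperature and seasonal
#'   amplitude (degC), peak near late July.
#' @param temp_ar1,temp_noise_sd AR(1) coefficient (in `[0, 1)`) and
#'   innovation sd of the temperature anomaly.
#' @param diurnal_range mean TX - TN spread (degC).
#' @param bucket_capacity_top,bucket_capacity_full store capacities (mm).
#' @param drainage drainage coefficient (mm/day at saturation).
#' @param seed integer seed; every random stream derives from it.
#' @return a list of class `synthetic_site_config`.
#' @export
synthetic_site_config <- function(years = 72L, start_year = 1950L,
                                  latitude = 50, longitude = 10,
                                  precip_occ_mean = 0.45,
                                  precip_occ_amp = 0.10,
                                  gamma_shape = 0.8,
                                  gamma_scale_mean = 5,
                                  gamma_scale_amp = 1.5,
                                  temp_mean = 9, temp_amp = 8.5,
                                  temp_ar1 = 0.7, temp_noise_sd = 2,
                                  diurnal_range = 8,
                                  bucket_capacity_top = 120,
                                  bucket_capacity_full = 400,
                                  drainage = 1.2,
                                  seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(years >= 1, abs(latitude) < 90,
              precip_occ_mean > 0, precip_occ_mean < 1,
              precip_occ_amp >= 0,
              precip_occ_mean + precip_occ_amp < 1,
              precip_occ_mean - precip_occ_amp > 0,
              gamma_shape > 0, gamma_scale_mean > gamma_scale_amp,
              gamma_scale_amp >= 0,
              temp_ar1 >= 0, temp_ar1 < 1, temp_noise_sd >= 0,
              diurnal_range > 0, bucket_capacity_top > 0,
              bucket_capacity_full > 0, drainage >= 0)
  })
  structure(cfg, class = "synthetic_site_config")
}

# One global seed drives independent substreams per variable, so adding
# a stream never perturbs the others. Substream ids are fixed offsets.
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + id * 16807) %% 2147483647)
}

with_substream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, id))
  expr
}

#' Generate a full synthetic site table
#'
#' Produces a daily table in the canonical per-site input layout
#' (`Date, Doy, lon, lat, PREC, TG, TN, TX, PET, RG, AET, SM_top,
#' SM_full`). Identical configuration (including seed) yields an
#' identical table.
#'
#' Construction: `PREC = Bernoulli(p(doy)) * Gamma(shape, scale(doy))`;
#' `TG` = seasonal sinusoid + AR(1) anomaly; `TX`/`TN` = `TG` +/- half
#' the diurnal range widened by folded-normal noise (ordering holds by
#' construction); `RG`/`PET` from solar geometry and Hargreaves-Samani;
#' soil moisture via the leaky bucket
#' `SM[t+1] = clip(SM[t] + (PREC - PET*SM - drainage*SM)/capacity, 0, 1)`;
#' `AET = PET * SM_full`.
#'
#' @param config a [synthetic_site_config()].
#' @return `data.frame` with one row per day and the columns above.
#' @export
generate_site <- function(config = synthetic_site_config()) {
  stopifnot(inherits(config, "synthetic_site_config"))
  cfg <- config
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
               as.Date(sprintf("%d-12-31", cfg$start_year + cfg$years - 1L)),
               by = "day")
  nd <- length(dates)
  doy <- calendar_fields(dates)$doy
  phase <- 2 * pi * (doy - 201) / 365.25 # temperature peak ~Jul 20

  # precipitation: seasonal occurrence (wet winter) and scale (big summer)
  p_wet <- cfg$precip_occ_mean + cfg$precip_occ_amp * cos(phase + pi)
  sc <- cfg$gamma_scale_mean + cfg$gamma_scale_amp * cos(phase)
  wet <- with_substream(cfg$seed, 1L, stats::runif(nd) < p_wet)
  amount <- with_substream(cfg$seed, 2L,
                           stats::rgamma(nd, shape = cfg$gamma_shape,
                                         scale = sc))
  prec <- ifelse(wet, amount, 0)

  # temperature: sinusoid + AR(1) anomaly
  anom <- with_substream(cfg$seed, 3L, {
    e <- stats::rnorm(nd, sd = cfg$temp_noise_sd)
    stats::filter(e, cfg$temp_ar1, method = "recursive")
  })
  tg <- cfg$temp_mean + cfg$temp_amp * cos(phase) + as.numeric(anom)
  spread <- with_substream(cfg$seed, 4L,
                           abs(stats::rnorm(nd, sd = cfg$diurnal_range / 6)))
  tx <- tg + cfg$diurnal_range / 2 + spread
  tn <- tg - cfg$diurnal_range / 2 - spread

  pr <- pet_for_site(dates, tg, tx, tn, cfg$latitude)

  bucket <- function(capacity) {
    sm <- numeric(nd)
    s <- 0.5
    for (t in seq_len(nd)) {
      s <- s + (prec[t] - pr$PET[t] * s - cfg$drainage * s) / capacity
      s <- min(max(s, 0), 1)
      sm[t] <- s
    }
    sm
  }
  sm_top <- bucket(cfg$bucket_capacity_top)
  sm_full <- bucket(cfg$bucket_capacity_full)

  data.frame(Date = dates, Doy = doy,
             lon = cfg$longitude, lat = cfg$latitude,
             PREC = prec, TG = tg, TN = tn, TX = tx,
             PET = pr$PET, RG = pr$RG,
             AET = pr$PET * sm_full,
             SM_top = sm_top, SM_full = sm_full)
}

#' Daily draws from a known zero-inflated Gamma, with exact oracles
#'
#' Test harness for distribution-recovery experiments: every day is an
#' independent draw from `Bernoulli(1 - q) * Gamma(shape, scale)`. The
#' returned oracles give the *exact* distribution both of the daily
#' values and of any `k`-day sum (a Binomial mixture of Gamma
#' convolutions), so the kernel pipeline can be checked against closed
#' -form truth.
#'
#' @param shape,scale Gamma parameters of the wet-day magnitude.
#' @param q probability of an exact zero (must be `< 1`).
#' @param years number of calendar years (default 72).
#' @param start_year first year (default 1950).
#' @param seed integer seed.
#' @return list with `series` (a [daily_series()]), and functions
#'   `cdf(x)` (exact daily mixture cdf, with `F(0) = q`),
#'   `cdf_sum(x, k)` (exact cdf of a `k`-day sum) and
#'   `sdi(x, k = 1, n = NULL)` (exact standard-normal score of `x`
#'   under the true distribution, optionally clipped like a sample of
#'   size `n`).
#' @export
generate_known_distribution <- function(shape = 2, scale = 5, q = 0.3,
                                        years = 72L, start_year = 1950L,
                                        seed = 1L) {
  stopifnot(shape > 0, scale > 0, q >= 0, years >= 1)
  if (q >= 1) stop("generate_known_distribution: q must be < 1 (degenerate)")
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1L)),
               by = "day")
  nd <- length(dates)
  vals <- with_substream(seed, 11L, {
    wet <- stats::runif(nd) >= q
    ifelse(wet, stats::rgamma(nd, shape = shape, scale = scale), 0)
  })
  cdf <- function(x) {
    q + (1 - q) * stats::pgamma(x, shape = shape, scale = scale)
  }
  cdf_sum <- function(x, k) {
    # sum of k iid zero-inflated gammas: mix over the Binomial wet count
    m <- 0:k
    w <- stats::dbinom(m, k, 1 - q)
    vapply(x, function(xx) {
      comp <- ifelse(m == 0, as.numeric(xx >= 0),
                     stats::pgamma(xx, shape = shape * m, scale = scale))
      sum(w * comp)
    }, numeric(1))
  }
  sdi <- function(x, k = 1L, n = NULL) {
    f <- if (k == 1L) cdf(x) else cdf_sum(x, k)
    if (!is.null(n)) f <- clip_probability(f, n)
    stats::qnorm(f)
  }
  list(series = daily_series(dates, vals, units = "mm"),
       cdf = cdf, cdf_sum = cdf_sum, sdi = sdi,
       params = list(shape = shape, scale = scale, q = q))
}
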
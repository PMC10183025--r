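# Per-calendar-day standardization of an (already aggregated) series.
#
# For every calendar day (month, day) the cross-year sample of
# non-missing values is collected (Feb 29 pooled with Feb 28), a
# distribution model is fitted (zero-inflated kernel mixture for
# precipitation, plain Gaussian-kernel model otherwise), and every
# year's value on that day is mapped to its clipped standard-normal
# score. Days whose climatology is degenerate (all values identical, or
# no wet day ever for precipitation) yield NA and a single collected
# warning. No state crosses calendar days.
standardize_by_calendar_day <- function(series, kind, min_sample_size = 30L,
                                        wet_threshold = 0, pool_days = 0L) {
  cf <- calendar_fields(series$dates)
  md <- cf$month * 100L + cf$day
  md[md == 229L] <- 228L # Feb 29 pooled with Feb 28
  # canonical 365-slot calendar position for optional neighbour pooling
  slot <- calendar_slot365(md %/% 100L, md %% 100L)
  out <- rep(NA_real_, length(series$values))
  degenerate <- character(0)
  for (key in unique(md)) {
    idx <- which(md == key)
    vals <- series$values[idx]
    ok <- !is.na(vals)
    if (pool_days > 0L) {
      ctr <- slot[idx[1]]
      win <- ((ctr - pool_days):(ctr + pool_days) - 1L) %% 365L + 1L
      pooled <- series$values[slot %in% win]
      sample <- pooled[!is.na(pooled)]
    } else {
      sample <- vals[ok]
    }
    if (length(sample) < min_sample_size) {
      stop(sprintf(paste0("standardization: only %d usable years for ",
                          "calendar day %02d-%02d (need >= %d); shorten the ",
                          "aggregation periods or lower min_sample_size"),
                   length(sample), key %/% 100L, key %% 100L,
                   min_sample_size))
    }
    n <- length(sample)
    f <- tryCatch({
      if (kind == "precipitation") {
        m <- zero_inflated_model(sample, wet_threshold = wet_threshold)
        zero_inflated_cdf(m, vals[ok])
      } else {
        if (length(unique(sample)) < 2L) stop("degenerate")
        m <- kde_model(sample)
        kde_cdf(m, vals[ok])
      }
    }, error = function(e) NULL)
    if (is.null(f)) {
      degenerate <- c(degenerate, sprintf("%02d-%02d", key %/% 100L,
                                          key %% 100L))
      next
    }
    out[idx[ok]] <- probability_to_sdi(clip_probability(f, n))
  }
  if (length(degenerate) > 0) {
    warning(sprintf("degenerate climatology on calendar day(s) %s: index set to NA",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  out
}

new_sdi_table <- function(dates, columns, index) {
  df <- data.frame(Date = dates)
  for (nm in names(columns)) df[[nm]] <- columns[[nm]]
  structure(df, index = index, class = c("sdi_table", "data.frame"))
}

#' Blank index table with the published column layout
#'
#' Constructs an (all-`NA`) index table carrying the canonical column
#' names (`SPI_5 ... SPI_720` etc.) for a given aggregation scheme —
#' useful for schema checks and incremental filling.
#'
#' @param dates `Date` vector.
#' @param index `"SPI"`, `"SPEI"` or `"SSMI"`.
#' @param periods aggregation periods (ignored for SSMI, whose columns
#'   are `SSMI_top` and `SSMI_full`).
#' @return an `sdi_table`.
#' @export
sdi_table_skeleton <- function(dates, index = c("SPI", "SPEI", "SSMI"),
                               periods = default_aggregation_periods()) {
  index <- match.arg(index)
  nms <- if (index == "SSMI") c("SSMI_top", "SSMI_full")
         else paste0(index, "_", check_aggregation_periods(periods))
  cols <- stats::setNames(rep(list(rep(NA_real_, length(dates))), length(nms)),
                          nms)
  new_sdi_table(as.Date(dates), cols, index)
}

#' Standardized Precipitation Index
#'
#' For each aggregation period `k`, precipitation is summed over the
#' trailing `k`-day window, each calendar day's cross-year sample of
#' aggregated sums is modelled with the zero-inflated kernel mixture,
#' and each day's value is transformed to its standard-normal score.
#' Fully deterministic: no randomness anywhere in the pipeline.
#'
#' @param precip a [daily_series()] of daily precipitation (mm, `>= 0`).
#' @param periods integer vector of aggregation periods in days
#'   (default [default_aggregation_periods()]).
#' @param min_sample_size minimum cross-year sample size per calendar
#'   day (default 30).
#' @param wet_threshold precipitation at or below this counts as a dry
#'   day (default 0 mm).
#' @param min_frac window completeness threshold of
#'   [aggregate_rolling()].
#' @param pool_days half-width (days) of optional neighbouring-calendar-day
#'   pooling used to enlarge short climatologies (default 0: strict
#'   per-day samples).
#' @return an `sdi_table` with columns `Date`, `SPI_<k>` for each `k`.
#' @export
compute_spi <- function(precip, periods = default_aggregation_periods(),
                        min_sample_size = 30L, wet_threshold = 0,
                        min_frac = 0.9, pool_days = 0L) {
  stopifnot_daily(precip, "precip")
  if (any(!is.na(precip$values) & precip$values < 0)) {
    stop("compute_spi: precipitation must be >= 0")
  }
  periods <- check_aggregation_periods(periods)
  cols <- list()
  for (k in periods) {
    agg <- aggregate_rolling(precip, k, min_frac = min_frac)
    cols[[paste0("SPI_", k)]] <-
      standardize_by_calendar_day(agg, "precipitation",
                                  min_sample_size = min_sample_size,
                                  wet_threshold = wet_threshold,
                                  pool_days = pool_days)
  }
  new_sdi_table(precip$dates, cols, "SPI")
}

#' Standardized Precipitation Evapotranspiration Index
#'
#' The daily climatic water balance `D = P - PET` is aggregated over
#' each trailing `k`-day window and standardized per calendar day with
#' the plain (not zero-inflated) kernel pathway, since `D` is real
#' valued with no atom.
#'
#' @param precip daily precipitation (mm) as a [daily_series()].
#' @param pet daily potential evapotranspiration (mm) on the identical
#'   calendar.
#' @inheritParams compute_spi
#' @return an `sdi_table` with columns `Date`, `SPEI_<k>`.
#' @export
compute_spei <- function(precip, pet, periods = default_aggregation_periods(),
                         min_sample_size = 30L, min_frac = 0.9,
                         pool_days = 0L) {
  stopifnot_daily(precip, "precip")
  stopifnot_daily(pet, "pet")
  if (length(precip$dates) != length(pet$dates) ||
      any(precip$dates != pet$dates)) {
    stop("compute_spei: precip and pet must share an identical daily calendar")
  }
  periods <- check_aggregation_periods(periods)
  d <- daily_series(precip$dates, precip$values - pet$values, units = "mm")
  cols <- list()
  for (k in periods) {
    agg <- aggregate_rolling(d, k, min_frac = min_frac)
    cols[[paste0("SPEI_", k)]] <-
      standardize_by_calendar_day(agg, "water_balance",
                                  min_sample_size = min_sample_size,
                                  pool_days = pool_days)
  }
  new_sdi_table(precip$dates, cols, "SPEI")
}

#' Standardized Soil Moisture Index
#'
#' Soil moisture integrates past meteorology by itself, so no rolling
#' aggregation is applied: each calendar day's cross-year sample of raw
#' daily soil moisture is standardized directly with the plain kernel
#' pathway.
#'
#' @param sm daily soil moisture as a [daily_series()], dimensionless in
#'   `[0, 1]` where non-missing.
#' @param layer `"top"` (upper ~30 cm) or `"full"` (whole ~200 cm
#'   profile); only sets the output column name.
#' @inheritParams compute_spi
#' @return an `sdi_table` with columns `Date`, `SSMI_top` or `SSMI_full`.
#' @export
compute_ssmi <- function(sm, layer = c("top", "full"),
                         min_sample_size = 30L, pool_days = 0L) {
  layer <- match.arg(layer)
  stopifnot_daily(sm, "sm")
  v <- sm$values
  if (any(!is.na(v) & (v < 0 | v > 1))) {
    stop("compute_ssmi: soil moisture must lie in [0, 1]")
  }
  vals <- standardize_by_calendar_day(sm, "soil_moisture",
                                      min_sample_size = min_sample_size,
                                      pool_days = pool_days)
  cols <- stats::setNames(list(vals), paste0("SSMI_", layer))
  new_sdi_table(sm$dates, cols, "SSMI")
}
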
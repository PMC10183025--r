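#' Calendar-aware daily time series
#'
#' A `daily_series` is the basic container of the package: one variable
#' observed on strictly consecutive Gregorian calendar days, with `NA` as
#' the explicit missing-value marker.
#'
#' @param dates `Date` vector (or parseable `"YYYY-MM-DD"` strings) of
#'   strictly consecutive calendar days.
#' @param values numeric vector of the same length; `NA` marks a missing
#'   day. Infinite values are rejected.
#' @param units free-text unit tag (e.g. `"mm"`, `"degC"`, `"dimensionless"`).
#'
#' @return An object of class `daily_series`: a list with elements
#'   `dates`, `values` and `units`.
#' @examples
#' p <- daily_series(seq(as.Date("2000-01-01"), by = "day", length.out = 10),
#'                   rexp(10), units = "mm")
#' @export
daily_series <- function(dates, values, units = "") {
  dates <- as.Date(dates)
  if (anyNA(dates)) {
    stop("daily_series: dates contain unparseable or missing entries")
  }
  if (length(dates) != length(values)) {
    stop("daily_series: length(dates) != length(values)")
  }
  if (length(dates) > 1L) {
    dd <- diff(as.integer(dates))
    if (any(dd != 1L)) {
      stop("daily_series: dates must be strictly consecutive calendar days")
    }
  }
  values <- as.numeric(values)
  if (any(is.infinite(values))) {
    stop("daily_series: values must be finite or NA, not infinite")
  }
  structure(list(dates = dates, values = values, units = units),
            class = "daily_series")
}

#' @export
length.daily_series <- function(x) length(x$values)

#' @export
print.daily_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<daily_series> %d days (%s .. %s)%s, %d missing\n",
              n, format(min(x$dates)), format(max(x$dates)),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.daily_series <- function(x, ...) {
  data.frame(Date = x$dates, value = x$values)
}

is_daily_series <- function(x) inherits(x, "daily_series")

stopifnot_daily <- function(x, arg = "series") {
  if (!is_daily_series(x)) stop(sprintf("%s must be a daily_series", arg))
  invisible(x)
}

# Fast calendar decomposition, computed once per series.
calendar_fields <- function(dates) {
  lt <- as.POSIXlt(dates)
  list(year = lt$year + 1900L, month = lt$mon + 1L, day = lt$mday,
       doy = lt$yday + 1L)
}

# Position of (month, day) in a canonical 365-day (non-leap) year;
# Feb 29 shares Feb 28's slot. Pure arithmetic: no date parsing.
calendar_slot365 <- function(month, day) {
  offset <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L,
              304L, 334L)
  offset[month] + pmin(day, ifelse(month == 2L, 28L, 31L))
}

#' Trailing rolling aggregation
#'
#' Sums each variable over the trailing `k`-day window that ends on and
#' includes the index day. This is the aggregation underlying SPI_k and
#' SPEI_k: the value on day *j* summarizes the conditions over days
#' *j - k + 1 .. j*.
#'
#' The first `k - 1` days are always missing. A window yields a missing
#' aggregate if the fraction of non-missing days within it falls below
#' `min_frac` (default 0.9); a partially complete window above the
#' threshold is rescaled to the full window length (`k * mean` of the
#' present values) so that aggregates stay comparable across windows.
#'
#' @param series a [daily_series()].
#' @param k positive integer window length in days.
#' @param min_frac minimum fraction of non-missing days a window needs
#'   (in (0, 1]); windows below it are set to `NA`.
#' @return a `daily_series` of the same calendar with aggregated values.
#' @examples
#' s <- daily_series(seq(as.Date("2000-01-01"), by = "day", length.out = 5), 1:5)
#' aggregate_rolling(s, 3)$values  # NA NA 6 9 12
#' @export
aggregate_rolling <- function(series, k, min_frac = 0.9) {
  stopifnot_daily(series)
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("aggregate_rolling: k must be a single integer >= 1")
  }
  if (min_frac <= 0 || min_frac > 1) {
    stop("aggregate_rolling: min_frac must be in (0, 1]")
  }
  k <- as.integer(k)
  v <- series$values
  n <- length(v)
  if (k == 1L) return(series)
  # running sums over present values and running counts of present days
  pres <- !is.na(v)
  v0 <- ifelse(pres, v, 0)
  cs <- cumsum(v0)
  cn <- cumsum(as.numeric(pres))
  out <- rep(NA_real_, n)
  if (n >= k) {
    j <- k:n
    wsum <- cs[j] - c(0, cs)[j - k + 1L]
    wcnt <- cn[j] - c(0, cn)[j - k + 1L]
    need <- ceiling(min_frac * k)
    ok <- wcnt >= need & wcnt > 0
    # rescale partial windows to full length
    out[j][ok] <- (wsum[ok] / wcnt[ok]) * k
  }
  daily_series(series$dates, out, units = series$units)
}

#' Default aggregation periods
#'
#' The canonical set of aggregation timescales: 5 to 365 days in steps of
#' 5, then 370 to 720 days in steps of 10 (109 periods in total),
#' spanning meteorological through multi-year hydrological drought.
#'
#' @return integer vector of 109 strictly increasing day counts.
#' @export
default_aggregation_periods <- function() {
  as.integer(c(seq(5L, 365L, by = 5L), seq(370L, 720L, by = 10L)))
}

check_aggregation_periods <- function(periods) {
  periods <- as.integer(periods)
  if (length(periods) < 1L || anyNA(periods) || any(periods < 1L)) {
    stop("aggregation periods must be positive integers")
  }
  if (is.unsorted(periods, strictly = TRUE)) {
    stop("aggregation periods must be strictly increasing")
  }
  periods
}

#' Cross-year climatological sample for one calendar day
#'
#' Collects, for a fixed calendar day (month, day), the value of an
#' (already aggregated) daily series in every year where that day is
#' non-missing. This cross-year sample is what the per-day distribution
#' is estimated from.
#'
#' Feb 29 is pooled with Feb 28: requesting either (2, 28) or (2, 29)
#' returns the union of all Feb 28 and Feb 29 values, so leap years
#' contribute two values and the sample never drops to a quarter of the
#' record length.
#'
#' @param series a [daily_series()], typically the output of
#'   [aggregate_rolling()].
#' @param month,day calendar day selector.
#' @param min_sample_size minimum acceptable sample size (default 30
#'   years, the accepted floor for robust climatological estimation);
#'   smaller samples raise an error. Use `0` to disable.
#' @return a list of class `climatological_sample` with elements
#'   `month`, `day`, `years`, `values`, `n`.
#' @export
climatological_sample <- function(series, month, day, min_sample_size = 30L) {
  stopifnot_daily(series)
  if (month < 1 || month > 12 || day < 1 || day > 31) {
    stop("climatological_sample: invalid (month, day)")
  }
  cf <- calendar_fields(series$dates)
  if (month == 2 && day %in% c(28, 29)) {
    sel <- cf$month == 2L & cf$day %in% c(28L, 29L)
  } else {
    sel <- cf$month == month & cf$day == day
  }
  ok <- sel & !is.na(series$values)
  yrs <- cf$year[ok]
  vals <- series$values[ok]
  o <- order(yrs)
  yrs <- yrs[o]; vals <- vals[o]
  if (length(vals) < min_sample_size) {
    stop(sprintf(paste0("climatological_sample: only %d usable years for ",
                        "(%02d-%02d); robust climatological estimation needs ",
                        "at least %d"),
                 length(vals), month, day, min_sample_size))
  }
  structure(list(month = as.integer(month), day = as.integer(day),
                 years = yrs, values = vals, n = length(vals)),
            class = "climatological_sample")
}
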
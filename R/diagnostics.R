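#' Normalized root-mean-square error
#'
#' RMSE over the paired non-missing values, divided by a spread measure
#' of the observations: their standard deviation (default), mean, or
#' range.
#'
#' @param obs,sim numeric vectors of equal length.
#' @param normalization `"sd"` (default), `"mean"` or `"range"`.
#' @return nonnegative scalar.
#' @export
nrmse <- function(obs, sim, normalization = c("sd", "mean", "range")) {
  normalization <- match.arg(normalization)
  p <- paired(obs, sim, min_pairs = 2L)
  denom <- switch(normalization,
                  sd = stats::sd(p$obs),
                  mean = mean(p$obs),
                  range = diff(range(p$obs)))
  if (!is.finite(denom) || denom == 0) {
    stop("nrmse: normalization denominator is zero (constant observations?)")
  }
  sqrt(mean((p$obs - p$sim)^2)) / denom
}

#' Squared Pearson correlation
#'
#' @param obs,sim numeric vectors of equal length; at least 3 complete
#'   pairs and positive variance on both sides are required.
#' @return value in `[0, 1]`.
#' @export
r_squared <- function(obs, sim) {
  p <- paired(obs, sim, min_pairs = 3L)
  if (stats::var(p$obs) == 0 || stats::var(p$sim) == 0) {
    stop("r_squared: zero variance in obs or sim")
  }
  stats::cor(p$obs, p$sim)^2
}

paired <- function(obs, sim, min_pairs) {
  if (length(obs) != length(sim)) stop("obs and sim must have equal length")
  ok <- !is.na(obs) & !is.na(sim)
  if (sum(ok) < min_pairs) {
    stop(sprintf("need at least %d complete (obs, sim) pairs", min_pairs))
  }
  list(obs = obs[ok], sim = sim[ok])
}

#' Standardize a series to mean 0, sd 1
#'
#' `(x - mean)/sd` over the non-missing entries; used e.g. to put soil
#' moisture from different sources on a common scale before comparison.
#'
#' @param x numeric vector (`NA` preserved).
#' @return standardized vector.
#' @export
standardize <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("standardize: zero variance")
  (x - m) / s
}

#' Day-of-year z-transformation
#'
#' Standardizes each value against the cross-year mean and sd of its own
#' calendar day (Feb 29 pooled with Feb 28), removing the mean seasonal
#' cycle — e.g. phenology in gross primary productivity — so that only
#' anomalies remain.
#'
#' @param series a [daily_series()].
#' @param min_years minimum cross-year sample per calendar day
#'   (default 3); days with fewer values, or zero within-day variance,
#'   yield `NA` (the latter with a warning).
#' @return a `daily_series` of per-day z-scores.
#' @export
doy_zscore <- function(series, min_years = 3L) {
  stopifnot_daily(series)
  cf <- calendar_fields(series$dates)
  md <- cf$month * 100L + cf$day
  md[md == 229L] <- 228L
  out <- rep(NA_real_, length(series$values))
  zero_var <- 0L
  for (key in unique(md)) {
    idx <- which(md == key)
    v <- series$values[idx]
    ok <- !is.na(v)
    if (sum(ok) < min_years) next
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0) { zero_var <- zero_var + 1L; next }
    out[idx] <- (v - mean(v[ok])) / s
  }
  if (zero_var > 0) {
    warning(sprintf("doy_zscore: %d calendar day(s) with zero cross-year variance set to NA",
                    zero_var), call. = FALSE)
  }
  daily_series(series$dates, out, units = "z-score")
}

#' Rolling correlation field between a response and an index table
#'
#' For each calendar day in the season and each index column, computes
#' the Pearson correlation between the response and the index over a
#' rolling calendar window (default 14 days, trailing), pooling the
#' window's paired values across all years. This is the standard way to
#' ask, day by day through the growing season, which drought timescale
#' the ecosystem response tracks best.
#'
#' @param response a [daily_series()], typically already
#'   [doy_zscore()]-transformed.
#' @param sdi_table an `sdi_table` on the same calendar.
#' @param window_days rolling window length in days (`>= 3`, default 14).
#' @param season integer months to evaluate (default `5:9`,
#'   May-September).
#' @param centered if `FALSE` (default) the window trails (ends on) the
#'   day; if `TRUE` it is centered on it.
#' @param min_pairs minimum number of complete pairs per cell
#'   (default 3); cells below it are `NA`.
#' @return matrix of correlations, one row per calendar day in the
#'   season (rownames `"MM-DD"`), one column per index column.
#' @export
rolling_correlation_field <- function(response, sdi_table, window_days = 14L,
                                      season = 5:9, centered = FALSE,
                                      min_pairs = 3L) {
  stopifnot_daily(response, "response")
  stopifnot(inherits(sdi_table, "sdi_table"))
  if (window_days < 3) stop("window_days must be >= 3")
  if (length(response$dates) != nrow(sdi_table) ||
      any(response$dates != sdi_table$Date)) {
    stop("response and sdi_table must share an identical daily calendar")
  }
  cf <- calendar_fields(response$dates)
  # canonical 365-day calendar position; Feb 29 shares Feb 28's slot
  ref <- calendar_slot365(cf$month, cf$day)
  cols <- setdiff(names(sdi_table), "Date")
  rows <- which(cf$month %in% season & !(cf$month == 2 & cf$day == 29))
  row_keys <- unique(ref[rows])
  row_keys <- row_keys[order(row_keys)]
  out <- matrix(NA_real_, nrow = length(row_keys), ncol = length(cols),
                dimnames = list(NULL, cols))
  half <- if (centered) window_days %/% 2L else 0L
  for (r in seq_along(row_keys)) {
    pos <- row_keys[r]
    lo <- pos - (window_days - 1L) + half
    hi <- pos + half
    win <- ((lo:hi - 1L) %% 365L) + 1L
    sel <- ref %in% win
    y <- response$values[sel]
    for (ci in seq_along(cols)) {
      x <- sdi_table[[cols[ci]]][sel]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= min_pairs &&
          stats::var(x[ok]) > 0 && stats::var(y[ok]) > 0) {
        out[r, ci] <- stats::cor(x[ok], y[ok])
      }
    }
  }
  lab <- format(as.Date(row_keys - 1L, origin = "2001-01-01"), "%m-%d")
  rownames(out) <- lab
  out
}
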
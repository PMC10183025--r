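#' Solar declination
#'
#' Declination of the sun for a given day of year, using the simple
#' sinusoidal approximation standard in reference-evapotranspiration
#' work: `0.409 * sin(2*pi*doy/365.25 - 1.39)`.
#'
#' @param doy day of year, in `[1, 366]` (vectorized).
#' @return declination in radians, bounded by `|delta| <= 0.409`.
#' @export
solar_declination <- function(doy) {
  check_doy(doy)
  0.409 * sin(2 * pi * doy / 365.25 - 1.39)
}

#' Inverse relative Earth-Sun distance
#'
#' Eccentricity correction factor `1 + 0.033 * cos(2*pi*doy/365.25)`,
#' dimensionless, in `[0.967, 1.033]`.
#'
#' @inheritParams solar_declination
#' @export
inverse_relative_distance <- function(doy) {
  check_doy(doy)
  1.0 + 0.033 * cos(2 * pi * doy / 365.25)
}

check_doy <- function(doy) {
  if (any(is.na(doy)) || any(doy < 1) || any(doy > 366)) {
    stop("day of year must lie in [1, 366]")
  }
  invisible(doy)
}

#' Sunrise hour angle
#'
#' `omega = arccos(-tan(lat) * tan(delta))`, with the argument clamped to
#' `[-1, 1]` so that polar day yields `omega = pi` and polar night
#' `omega = 0` instead of a domain error. High-latitude sites (ICOS
#' reaches ~68 degrees N) hit the clamp every winter and summer.
#'
#' @param lat_rad latitude in radians, `|lat| < pi/2`.
#' @param delta_rad solar declination in radians.
#' @return hour angle in radians, in `[0, pi]`.
#' @export
sunrise_hour_angle <- function(lat_rad, delta_rad) {
  if (any(abs(lat_rad) >= pi / 2)) {
    stop("latitude must satisfy |lat| < pi/2 radians (exclusive of the poles)")
  }
  arg <- -tan(lat_rad) * tan(delta_rad)
  acos(pmin(1, pmax(-1, arg)))
}

#' Extraterrestrial (top-of-atmosphere) radiation from latitude
#'
#' Daily extraterrestrial radiation from solar geometry only:
#'
#' `Ra = (24*60)/pi * 0.082 * dr * (omega*sin(lat)*sin(delta) +
#'   cos(lat)*cos(delta)*sin(omega))`
#'
#' with `0.082 MJ m-2 min-1` the solar constant, so the result is in
#' MJ m-2 day-1 (multiply by 11.574 for a mean W m-2). The hour-angle
#' clamp guarantees `Ra >= 0`; any residual negative rounding is floored
#' at zero (polar night).
#'
#' @param lat_rad latitude in radians.
#' @param doy day of year in `[1, 366]` (vectorized; recycled against
#'   `lat_rad`).
#' @return radiation in MJ m-2 day-1, `>= 0`.
#' @export
extraterrestrial_radiation <- function(lat_rad, doy) {
  check_doy(doy)
  delta <- solar_declination(doy)
  dr <- inverse_relative_distance(doy)
  omega <- sunrise_hour_angle(lat_rad, delta)
  ra <- (24 * 60) / pi * 0.082 * dr *
    (omega * sin(lat_rad) * sin(delta) + cos(lat_rad) * cos(delta) * sin(omega))
  pmax(ra, 0)
}

#' Hargreaves-Samani potential evapotranspiration
#'
#' `PET = 0.00023 * RG * sqrt(TX - TN) * (TG + 17.8)` in mm/day, the
#' parsimonious temperature-and-radiation PET model. `RG` is the
#' latitude-derived extraterrestrial radiation of
#' [extraterrestrial_radiation()]; the coefficient is a package constant
#' (`coef`) applied to that radiation exactly as stated.
#'
#' Negative results (possible when `TG < -17.8` degC) are floored at
#' zero: evaporative demand cannot be negative.
#'
#' @param tg,tx,tn daily mean, maximum and minimum air temperature
#'   (degC); must satisfy `TN <= TG <= TX` up to `tol`.
#' @param rg extraterrestrial radiation (MJ m-2 day-1), `>= 0`.
#' @param coef multiplicative coefficient (default 0.00023).
#' @param tol tolerance for the temperature-ordering check (degC).
#' @return PET in mm/day, `>= 0`. Vectorized; `NA` propagates.
#' @export
hargreaves_pet <- function(tg, tx, tn, rg, coef = 0.00023, tol = 1e-6) {
  cmp <- !is.na(tx) & !is.na(tn)
  if (any(cmp & (tx - tn < -tol))) {
    stop("hargreaves_pet: TX < TN")
  }
  if (any(!is.na(rg) & rg < 0)) {
    stop("hargreaves_pet: RG must be >= 0")
  }
  rng <- pmax(tx - tn, 0)
  pmax(coef * rg * sqrt(rng) * (tg + 17.8), 0)
}

#' PET and radiation columns for a site
#'
#' Convenience wrapper: computes `RG` from latitude and date, then
#' Hargreaves-Samani `PET` from the three temperature series.
#'
#' @param dates `Date` vector.
#' @param tg,tx,tn temperature series (degC).
#' @param lat_deg site latitude in decimal degrees.
#' @return `data.frame` with columns `RG` (MJ m-2 day-1) and `PET` (mm).
#' @export
pet_for_site <- function(dates, tg, tx, tn, lat_deg) {
  if (abs(lat_deg) >= 90) stop("latitude must be in (-90, 90) degrees")
  doy <- calendar_fields(as.Date(dates))$doy
  rg <- extraterrestrial_radiation(lat_deg * pi / 180, doy)
  data.frame(RG = rg, PET = hargreaves_pet(tg, tx, tn, rg))
}
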
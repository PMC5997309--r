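#' Low-precision solar position terms
#'
#' Equation of time and solar declination for a civil date, from the NOAA
#' low-precision formulas evaluated at 12:00 UTC. The same terms are used by
#' the twilight simulator and by the position estimator, so noise-free
#' round-trips close exactly.
#'
#' @param date Date vector (or anything coercible with `as.Date`).
#' @return data.frame with columns `eqtime` (minutes; apparent solar time
#'   minus mean time) and `decl` (solar declination, radians).
#' @export
solar_terms <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  # fractional year, radians, at civil noon
  g <- 2 * pi / 365 * (doy - 1 + 0.5 / 24 * 0)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  data.frame(eqtime = eqtime, decl = decl)
}

#' Twilight hour angle
#'
#' Hour angle (degrees) at which the sun crosses a given elevation, for a
#' latitude and solar declination. `NA` where the sun never reaches the
#' elevation (polar day or night at that elevation).
#'
#' @param lat latitude, decimal degrees.
#' @param decl solar declination, radians.
#' @param elevation sun elevation defining twilight, degrees (<= 0 for
#'   below-horizon thresholds).
#' @return hour angle in degrees, in (0, 180).
#' @export
twilight_hour_angle <- function(lat, decl, elevation = -3) {
  phi <- lat * pi / 180
  h0 <- elevation * pi / 180
  cosha <- (sin(h0) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cosha[cosha < -1 | cosha > 1] <- NA_real_
  acos(cosha) * 180 / pi
}

#' Dawn and dusk times at a known position
#'
#' Forward solar model: UTC times at which the sun crosses `elevation` at
#' (`lon`, `lat`) on `date`. Vectorised over all arguments.
#'
#' @inheritParams twilight_hour_angle
#' @param date Date vector.
#' @param lon longitude, decimal degrees (east positive).
#' @param apply_eqtime logical; set `FALSE` to zero the equation-of-time
#'   correction (useful for geometric checks).
#' @return data.frame with `date`, `dawn`, `dusk` (POSIXct UTC; `NA` when the
#'   sun does not cross the elevation that day).
#' @export
twilight_times <- function(date, lon, lat, elevation = -3, apply_eqtime = TRUE) {
  date <- as.Date(date)
  st <- solar_terms(date)
  eq <- if (apply_eqtime) st$eqtime else 0
  ha <- twilight_hour_angle(lat, st$decl, elevation)
  dawn_min <- 720 - 4 * (lon + ha) - eq
  dusk_min <- 720 - 4 * (lon - ha) - eq
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  data.frame(date = date,
             dawn = day0 + dawn_min * 60,
             dusk = day0 + dusk_min * 60)
}

# Day of year (1-based) on which the solar declination crosses zero, found by
# sign change of the low-precision declination series. `which` is "march" or
# "september".
.equinox_doy <- function(year, which = c("march", "september")) {
  which <- match.arg(which)
  days <- if (which == "march") 70:90 else 255:275
  dates <- as.Date(paste0(year, "-01-01")) + (days - 1)
  d <- solar_terms(dates)$decl
  i <- if (which == "march") which(d[-length(d)] < 0 & d[-1] >= 0)[1] else
    which(d[-length(d)] > 0 & d[-1] <= 0)[1]
  dates[i + 1]
}

#' Equinox dates for a set of years
#'
#' @param years integer vector of calendar years.
#' @return Date vector (two dates per year: March and September equinox).
#' @export
equinox_dates <- function(years) {
  years <- sort(unique(as.integer(years)))
  out <- lapply(years, function(y) c(.equinox_doy(y, "march"),
                                     .equinox_doy(y, "september")))
  do.call(c, out)
}

#' Flag dates close to an equinox
#'
#' Light-based latitude is unreliable near the equinoxes, when day length is
#' about 12 h everywhere. Dates within `window` days (inclusive) of the
#' nearest equinox are flagged.
#'
#' @param date Date vector.
#' @param window half-width of the exclusion window, days (default 20).
#' @return logical vector.
#' @export
near_equinox <- function(date, window = 20) {
  date <- as.Date(date)
  yrs <- unique(as.integer(strftime(date, "%Y")))
  eq <- equinox_dates(c(yrs - 1, yrs, yrs + 1))
  mind <- vapply(date, function(d) min(abs(as.numeric(d - eq))), numeric(1))
  mind <= window
}
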
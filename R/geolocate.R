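#' Detect twilight events in a raw light series
#'
#' Threshold method: a dawn is recorded at each upward crossing of the light
#' threshold and a dusk at each downward crossing, with the crossing time
#' interpolated linearly between the bracketing samples.
#'
#' @param light data.frame with columns `timestamp` (POSIXct, monotone,
#'   fixed sampling interval) and `light` (arbitrary logger units).
#' @param threshold light threshold (default 20).
#' @return data.frame `time` (POSIXct), `kind` ("dawn"/"dusk"). Empty (with
#'   a warning) if the series never crosses the threshold.
#' @export
detect_twilights <- function(light, threshold = 20) {
  stopifnot(all(diff(as.numeric(light$timestamp)) > 0))
  x <- light$light
  t <- as.numeric(light$timestamp)
  above <- x > threshold
  i <- which(diff(above) != 0)
  if (length(i) == 0L) {
    warning("light series never crosses the threshold; no twilights")
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), stringsAsFactors = FALSE))
  }
  frac <- (threshold - x[i]) / (x[i + 1L] - x[i])
  tc <- t[i] + frac * (t[i + 1L] - t[i])
  kind <- ifelse(x[i + 1L] > x[i], "dawn", "dusk")
  data.frame(time = as.POSIXct(tc, origin = "1970-01-01", tz = "UTC"),
             kind = kind, stringsAsFactors = FALSE)
}

#' Screen out burrow (incubation) days from a raw light series
#'
#' Days on which the logger never saw light above the threshold are read as
#' time spent inside the burrow (incubation shifts) and flagged for
#' exclusion; their twilights would be artefacts of shading, not of sunrise
#' or sunset.
#'
#' @param light data.frame with `timestamp` and `light`.
#' @param threshold light threshold (default 20).
#' @return data.frame `date`, `max_light`, `incubation` (logical).
#' @export
flag_incubation_days <- function(light, threshold = 20) {
  day <- as.Date(light$timestamp, tz = "UTC")
  mx <- tapply(light$light, day, max)
  data.frame(date = as.Date(names(mx)), max_light = as.numeric(mx),
             incubation = as.numeric(mx) < threshold, row.names = NULL)
}

# Latitude from twilight hour angle and declination, by root finding on the
# monotone day-length relation. Returns NA when no latitude matches.
.solve_latitude <- function(ha_deg, decl, elevation) {
  f <- function(phi) twilight_hour_angle(phi, decl, elevation) - ha_deg
  grid <- seq(-89.5, 89.5, by = 0.5)
  vals <- f(grid)
  ok <- which(!is.na(vals))
  if (length(ok) < 2L) return(NA_real_)
  s <- vals[ok]
  cross <- which(s[-length(s)] * s[-1L] <= 0)
  if (length(cross) == 0L) return(NA_real_)
  j <- cross[1L]
  stats::uniroot(f, c(grid[ok[j]], grid[ok[j + 1L]]), tol = 1e-7)$root
}

#' Position from one dawn/dusk pair
#'
#' Longitude follows from the offset of the dawn/dusk midpoint (local
#' apparent noon) from 12:00 UTC, with the equation of time applied;
#' latitude is solved from the day length and the solar declination. When
#' the day length is too close to 12 h to pin the latitude down (equinox
#' geometry), the position is flagged `latitude_indeterminate` and only the
#' longitude is returned.
#'
#' @param dawn,dusk POSIXct UTC twilight times of the same local day.
#' @param sun_elevation sun elevation of the light threshold, degrees.
#' @param apply_eqtime logical; zero the equation of time if `FALSE`.
#' @return one-row data.frame `lon`, `lat`, `flags` (";"-joined).
#' @export
position_from_twilight_pair <- function(dawn, dusk, sun_elevation = -3,
                                        apply_eqtime = TRUE) {
  if (dusk <= dawn) stop("dusk must follow dawn")
  date <- as.Date(dawn + (as.numeric(dusk) - as.numeric(dawn)) / 2)
  st <- solar_terms(date)
  eq <- if (apply_eqtime) st$eqtime else 0
  mid_min <- (as.numeric(dawn) + as.numeric(dusk)) / 2 / 60 -
    as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) / 60
  lon <- (720 - eq - mid_min) / 4
  ha <- as.numeric(difftime(dusk, dawn, units = "mins")) / 8  # degrees
  flags <- character()
  daylen_h <- as.numeric(difftime(dusk, dawn, units = "hours"))
  # near 12 h the day-length curve is flat in latitude: indeterminate
  lat <- NA_real_
  if (abs(st$decl) < 0.005) {
    flags <- c(flags, "latitude_indeterminate")
  } else {
    lat <- .solve_latitude(ha, st$decl, sun_elevation)
    if (is.na(lat)) flags <- c(flags, "latitude_indeterminate")
  }
  data.frame(lon = lon, lat = lat, flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Daily positions from a twilight table
#'
#' Applies [position_from_twilight_pair()] to each date's dawn/dusk pair,
#' giving the local-midday position of each day.
#'
#' @param twilights data.frame as from [simulate_twilights()] (`bird_id`,
#'   `date`, `dawn`, `dusk`, optional `flag`).
#' @inheritParams position_from_twilight_pair
#' @return data.frame `bird_id`, `date`, `kind`, `lon`, `lat`, `flags`.
#' @export
positions_from_twilights <- function(twilights, sun_elevation = -3) {
  rows <- lapply(seq_len(nrow(twilights)), function(i) {
    tw <- twilights[i, ]
    if (is.na(tw$dawn) || is.na(tw$dusk) ||
        (!is.null(tw$flag) && nzchar(tw$flag))) {
      return(data.frame(bird_id = tw$bird_id, date = tw$date, kind = "midday",
                        lon = NA_real_, lat = NA_real_, flags = "polar",
                        stringsAsFactors = FALSE))
    }
    p <- position_from_twilight_pair(tw$dawn, tw$dusk, sun_elevation)
    data.frame(bird_id = tw$bird_id, date = tw$date, kind = "midday",
               lon = p$lon, lat = p$lat, flags = p$flags,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag unreliable twilight transitions
#'
#' Adds `short_dark` where the dark span from dusk to the next dawn is under
#' `min_dark` hours, and `equinox` for dates within `equinox_window` days
#' (inclusive) of an equinox. Flags exclude the latitude of the affected
#' days downstream; nothing is deleted.
#'
#' @param twilights twilight table (`date`, `dawn`, `dusk`, ...).
#' @param min_dark minimum dark period, hours (default 4).
#' @param equinox_window half-width of the equinox exclusion, days
#'   (default 20, boundary inclusive).
#' @return the table with a `flags` column (";"-joined).
#' @export
filter_transitions <- function(twilights, min_dark = 4, equinox_window = 20) {
  tw <- twilights[order(twilights$date), ]
  n <- nrow(tw)
  dark_h <- c(as.numeric(difftime(tw$dawn[-1L], tw$dusk[-n], units = "hours")),
              NA_real_)
  short <- !is.na(dark_h) & dark_h < min_dark
  eq <- near_equinox(tw$date, equinox_window)
  tw$flags <- apply(cbind(short, eq), 1L, function(z)
    paste(c("short_dark", "equinox")[z], collapse = ";"))
  tw
}

# great-circle km between consecutive rows of a lon/lat matrix
.step_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2L) return(numeric(0))
  geosphere::distHaversine(cbind(lon[-n], lat[-n]), cbind(lon[-1L], lat[-1L]),
                           r = 6371000) / 1000
}

#' Cohort speed threshold
#'
#' The rejection threshold of the speed filter: the given percentile of the
#' per-bird maximum travel speeds across the processed cohort.
#'
#' @param tracks list of position data.frames (`date`, `lon`, `lat`, `flags`).
#' @param percentile percentile of per-bird maxima (default 95).
#' @return speed threshold, km/h.
#' @export
cohort_speed_threshold <- function(tracks, percentile = 95) {
  maxima <- vapply(tracks, function(tr) {
    tr <- tr[!is.na(tr$lat) & !nzchar(tr$flags), ]
    if (nrow(tr) < 2L) return(NA_real_)
    dt <- diff(as.numeric(as.Date(tr$date))) * 24
    max(.step_km(tr$lon, tr$lat) / dt)
  }, numeric(1))
  maxima <- maxima[!is.na(maxima)]
  if (length(maxima) == 0L) stop("no usable tracks")
  stats::quantile(maxima, percentile / 100, names = FALSE)
}

#' Iterative forward/backward-averaging speed filter
#'
#' For each retained fix, the mean of its incoming and outgoing great-circle
#' speeds is computed; while any fix exceeds `threshold_kmh`, the worst one
#' is flagged `speed_reject` and speeds are recomputed over the remaining
#' fixes. Removals are flags, never deletions.
#'
#' @param track position data.frame (`date`, `lon`, `lat`, `flags`).
#' @param threshold_kmh rejection threshold, km/h (see
#'   [cohort_speed_threshold()]).
#' @param max_iter iteration cap.
#' @return the track with `speed_reject` added to `flags` where rejected.
#' @export
speed_filter <- function(track, threshold_kmh, max_iter = 100) {
  usable <- !is.na(track$lat) & !nzchar(track$flags)
  if (sum(usable) < 3L) stop("track exhausted: fewer than 3 unflagged positions")
  keep <- usable
  for (it in seq_len(max_iter)) {
    idx <- which(keep)
    if (length(idx) < 3L) break
    lon <- track$lon[idx]; lat <- track$lat[idx]
    dt <- diff(as.numeric(as.Date(track$date[idx]))) * 24
    sp <- .step_km(lon, lat) / dt
    m <- length(idx)
    avg <- (c(NA, sp) + c(sp, NA)) / 2
    avg[1L] <- sp[1L]; avg[m] <- sp[m - 1L]
    if (all(avg <= threshold_kmh, na.rm = TRUE)) break
    worst <- idx[which.max(avg)]
    keep[worst] <- FALSE
  }
  rej <- usable & !keep
  track$flags[rej] <- ifelse(nzchar(track$flags[rej]),
                             paste0(track$flags[rej], ";speed_reject"),
                             "speed_reject")
  track
}

#' Departure and arrival dates of the non-breeding period
#'
#' Departure is the first date the bird's position lies outside the colony
#' radius, followed by `d_days` consecutive days of increasing distance from
#' the colony; arrival is the first date back inside the radius preceded by
#' `d_days` days of decreasing distance. If the positional arrival cannot be
#' determined (e.g. an equinox gap), the first night on which every
#' immersion record is dry (0) is used instead.
#'
#' @param track position data.frame (`date`, `lon`, `lat`, `flags`).
#' @param immersion optional immersion data.frame (`timestamp`, `wet_count`).
#' @param colony_lon,colony_lat colony position, degrees.
#' @param radius_km colony radius, km (default 200, about one geolocation
#'   error unit).
#' @param d_days days of directed movement required (default 3).
#' @return list `departure`, `arrival` (Dates or NA), `arrival_method`
#'   ("positional", "immersion" or NA), `resident` (logical).
#' @export
nonbreeding_window <- function(track, immersion = NULL,
                               colony_lon, colony_lat,
                               radius_km = 200, d_days = 3) {
  tr <- track[!is.na(track$lat) & !nzchar(track$flags), ]
  tr <- tr[order(tr$date), ]
  dist <- geosphere::distHaversine(cbind(tr$lon, tr$lat),
                                   c(colony_lon, colony_lat),
                                   r = 6371000) / 1000
  outside <- dist > radius_km
  n <- nrow(tr)
  departure <- NA
  for (i in which(outside)) {
    j <- i:min(n, i + d_days)
    if (length(j) > d_days && all(diff(dist[j]) > 0)) { departure <- tr$date[i]; break }
  }
  if (is.na(departure))
    return(list(departure = NA, arrival = NA, arrival_method = NA_character_,
                resident = TRUE))
  arrival <- NA; method <- NA_character_
  after <- which(tr$date > departure & !outside)
  for (i in after) {
    j <- max(1L, i - d_days):i
    if (length(j) > d_days && all(diff(dist[j]) < 0)) { arrival <- tr$date[i]; break }
  }
  if (!is.na(arrival)) {
    method <- "positional"
  } else if (!is.null(immersion)) {
    arrival <- .first_dry_night(immersion, after = departure)
    if (!is.na(arrival)) method <- "immersion"
  }
  list(departure = departure, arrival = arrival, arrival_method = method,
       resident = FALSE)
}

# First date (after `after`) whose night (18:00 UTC to 06:00 UTC next day,
# a conservative dark window at these longitudes) is entirely dry.
.first_dry_night <- function(immersion, after) {
  ts <- immersion$timestamp
  h <- as.integer(strftime(ts, "%H", tz = "UTC"))
  night_date <- as.Date(ts, tz = "UTC") - (h < 6)
  is_night <- h >= 18 | h < 6
  im <- data.frame(date = night_date[is_night],
                   wet = immersion$wet_count[is_night])
  agg <- stats::aggregate(wet ~ date, im, max)
  dry <- agg$date[agg$wet == 0 & agg$date > after + 10]
  if (length(dry) == 0L) return(NA)
  min(dry)
}
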
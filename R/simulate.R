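#' Default study colonies
#'
#' The four Macaronesian Bulwer's petrel colonies with their geographic
#' positions and breeding windows.
#'
#' @return data.frame with columns `name`, `archipelago`, `lat`, `lon`,
#'   `breeding_start`, `breeding_end` (month numbers).
#' @export
make_default_colonies <- function() {
  data.frame(
    name = c("Vila", "M. Clara", "Raso", "Cima"),
    archipelago = c("Azores", "Canary Islands", "Cape Verde", "Cape Verde"),
    lat = c(36.94, 29.29, 16.61, 14.97),
    lon = c(-25.17, -13.53, -24.58, -24.64),
    breeding_start = c(4L, 4L, 4L, 1L),
    breeding_end = c(10L, 9L, 10L, 8L),
    stringsAsFactors = FALSE
  )
}

#' Default non-breeding areas
#'
#' Bounding boxes for the two oceanic non-breeding regions, the Central and
#' South Atlantic. The boxes are emulation choices consistent with the
#' tropical mid-Atlantic and the area south of 10 deg S; they are disjoint
#' and configurable.
#'
#' @return data.frame with columns `name`, `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max`, `residency_days`.
#' @export
make_default_areas <- function() {
  data.frame(
    name = c("CentralAtlantic", "SouthAtlantic"),
    lon_min = c(-40, -40), lon_max = c(-15, 5),
    lat_min = c(-5, -35), lat_max = c(20, -15),
    residency_days = c(150L, 150L),
    stringsAsFactors = FALSE
  )
}

#' Feather isotope class parameters
#'
#' Published per-feather mean (SD) d15N and d13C values, by non-breeding
#' area (P1, S8, R6) and by colony (P1, S8, R6 of tracked birds). These are
#' the generating parameters of the synthetic feather model; the
#' d15N--d13C correlation is not reported and defaults to 0.
#'
#' @param correlation within-class correlation between d15N and d13C,
#'   in (-1, 1); default 0.
#' @return data.frame with columns `feather`, `label_by` ("area" or
#'   "colony"), `label`, `mean_d15N`, `sd_d15N`, `mean_d13C`, `sd_d13C`,
#'   `correlation`.
#' @export
make_default_isotope_params <- function(correlation = 0) {
  stopifnot(correlation > -1, correlation < 1)
  area <- data.frame(
    feather = rep(c("P1", "S8", "R6"), each = 2),
    label_by = "area",
    label = rep(c("CentralAtlantic", "SouthAtlantic"), 3),
    mean_d15N = c(12.5, 12.5, 13.1, 14.6, 12.8, 15.0),
    sd_d15N   = c(0.6, 0.7, 0.8, 1.3, 1.2, 1.6),
    mean_d13C = c(-16.5, -16.5, -16.3, -16.8, -16.5, -17.2),
    sd_d13C   = c(0.3, 0.3, 0.3, 0.3, 0.4, 0.5),
    stringsAsFactors = FALSE
  )
  cols <- c("Vila", "M. Clara", "Raso", "Cima")
  colony <- data.frame(
    feather = rep(c("P1", "S8", "R6"), each = 4),
    label_by = "colony",
    label = rep(cols, 3),
    mean_d15N = c(11.9, 12.7, 12.3, 12.6, 13.8, 13.9, 13.4, 13.1,
                  13.8, 13.9, 13.2, 13.0),
    sd_d15N   = c(0.4, 0.7, 0.5, 0.4, 0.8, 1.5, 0.9, 0.6,
                  2.3, 1.8, 1.3, 1.2),
    mean_d13C = c(-16.2, -16.6, -16.4, -16.5, -16.4, -16.6, -16.3, -16.3,
                  -16.7, -17.0, -16.5, -16.5),
    sd_d13C   = c(0.3, 0.3, 0.2, 0.3, 0.4, 0.5, 0.2, 0.2,
                  0.4, 0.7, 0.3, 0.3),
    stringsAsFactors = FALSE
  )
  out <- rbind(area, colony)
  out$correlation <- correlation
  out
}

# Great-circle interpolation between two lon/lat points at a daily speed cap.
# Returns the travel positions (excluding endpoints), one per day.
.migration_leg <- function(from, to, max_speed_km) {
  d <- geosphere::distHaversine(from, to, r = 6371000) / 1000
  n_days <- max(1L, ceiling(d / max_speed_km))
  if (n_days == 1L) return(NULL)
  f <- seq_len(n_days - 1L) / n_days
  geosphere::gcIntermediate(from, to, n = n_days - 1L, addStartEnd = FALSE)
}

#' Simulate annual tracks with a scripted non-breeding period
#'
#' Each bird stays near its colony, departs on a scripted date, migrates
#' along the great circle to a point inside its non-breeding area at no more
#' than `max_speed_km` per day, performs a reflecting random walk inside the
#' area box for its residency, and returns. The fraction `area_mix` of birds
#' is assigned to the second (South Atlantic) area.
#'
#' @param colonies data.frame as from [make_default_colonies()].
#' @param areas data.frame as from [make_default_areas()].
#' @param n_birds number of birds (>= 1).
#' @param area_mix fraction of birds assigned to the second area, in [0, 1].
#' @param year calendar year in which departure falls.
#' @param max_speed_km migration speed cap, km/day.
#' @param colony_sd_deg SD of day-to-day scatter around the colony, degrees.
#' @param walk_sd_deg daily step SD of the residency random walk, degrees.
#' @param seed RNG seed; same seed gives identical output.
#' @return list of tracks; each a list with `bird_id`, `colony`, `area`,
#'   `departure`, `arrival` (Dates) and `positions` (data.frame `date`,
#'   `lon`, `lat`).
#' @export
simulate_tracks <- function(colonies = make_default_colonies(),
                            areas = make_default_areas(),
                            n_birds, area_mix = 0.25, year = 2012,
                            max_speed_km = 700, colony_sd_deg = 0.1,
                            walk_sd_deg = 0.6, seed = 1) {
  stopifnot(n_birds >= 1, area_mix >= 0, area_mix <= 1)
  if (nrow(colonies) == 0L) stop("empty colony list")
  if (nrow(areas) == 0L) stop("empty area list")
  set.seed(seed)
  n_south <- round(n_birds * area_mix)
  is_south <- sample(rep(c(TRUE, FALSE), c(n_south, n_birds - n_south)))
  lapply(seq_len(n_birds), function(i) {
    col <- colonies[((i - 1L) %% nrow(colonies)) + 1L, ]
    area <- if (is_south[i] && nrow(areas) > 1L) areas[2L, ] else areas[1L, ]
    dep <- as.Date(sprintf("%d-%02d-15", year, col$breeding_end)) +
      sample(-10:10, 1)
    resid_days <- area$residency_days + sample(0:30, 1)
    # target point well inside the box
    tx <- stats::runif(1, area$lon_min + 2, area$lon_max - 2)
    ty <- stats::runif(1, area$lat_min + 2, area$lat_max - 2)
    pre_days <- 30L
    pre <- cbind(lon = col$lon + stats::rnorm(pre_days, 0, colony_sd_deg),
                 lat = col$lat + stats::rnorm(pre_days, 0, colony_sd_deg))
    leg_out <- .migration_leg(c(col$lon, col$lat), c(tx, ty), max_speed_km)
    # reflecting random walk inside the box
    res <- matrix(NA_real_, resid_days, 2)
    p <- c(tx, ty)
    for (d in seq_len(resid_days)) {
      p <- p + stats::rnorm(2, 0, walk_sd_deg)
      p[1] <- .reflect(p[1], area$lon_min + 0.5, area$lon_max - 0.5)
      p[2] <- .reflect(p[2], area$lat_min + 0.5, area$lat_max - 0.5)
      res[d, ] <- p
    }
    leg_back <- .migration_leg(p, c(col$lon, col$lat), max_speed_km)
    post_days <- 30L
    post <- cbind(lon = col$lon + stats::rnorm(post_days, 0, colony_sd_deg),
                  lat = col$lat + stats::rnorm(post_days, 0, colony_sd_deg))
    pos <- rbind(pre, leg_out, res, leg_back, post)
    dates <- dep - pre_days + seq_len(nrow(pos)) - 1L
    arrival <- dates[pre_days + NROW(leg_out) + resid_days + NROW(leg_back) + 1L]
    list(bird_id = sprintf("bird%03d", i),
         colony = col$name, area = area$name,
         departure = dep, arrival = arrival,
         positions = data.frame(date = dates, lon = pos[, 1], lat = pos[, 2]))
  })
}

.reflect <- function(x, lo, hi) {
  while (x < lo || x > hi) x <- ifelse(x < lo, 2 * lo - x, 2 * hi - x)
  x
}

#' Simulate twilight times along a track
#'
#' Forward model: dawn and dusk UTC times computed from solar geometry at
#' each day's true position, plus Gaussian timing noise. Days on which the
#' sun never crosses the elevation are emitted with `flag = "polar"`.
#'
#' @param track one track from [simulate_tracks()].
#' @param sun_elevation sun elevation defining twilight, degrees in (-18, 0].
#' @param noise_sd twilight timing noise SD, minutes.
#' @param seed RNG seed.
#' @return data.frame `bird_id`, `date`, `dawn`, `dusk` (POSIXct UTC),
#'   `flag` ("" or "polar").
#' @export
simulate_twilights <- function(track, sun_elevation = -3, noise_sd = 2,
                               seed = 1) {
  stopifnot(sun_elevation > -18, sun_elevation <= 0, noise_sd >= 0)
  pos <- track$positions
  if (is.null(pos) || nrow(pos) == 0L) stop("track with no positions")
  set.seed(seed)
  tw <- twilight_times(pos$date, pos$lon, pos$lat, elevation = sun_elevation)
  n <- nrow(tw)
  tw$dawn <- tw$dawn + stats::rnorm(n, 0, noise_sd) * 60
  tw$dusk <- tw$dusk + stats::rnorm(n, 0, noise_sd) * 60
  data.frame(bird_id = track$bird_id, date = tw$date,
             dawn = tw$dawn, dusk = tw$dusk,
             flag = ifelse(is.na(tw$dawn) | is.na(tw$dusk), "polar", ""),
             stringsAsFactors = FALSE)
}

#' Simulate saltwater-immersion records along a track
#'
#' Ten-minute wet counts in 0..200 (0 = continuously dry, 200 = continuously
#' wet). Nights spent at the colony (before departure and after arrival) are
#' entirely dry, emulating a bird inside its burrow; at-sea periods mix
#' flight (dry) and sitting on the water (wet).
#'
#' @param track one track from [simulate_tracks()].
#' @param p_wet probability that any at-sea 10-min block is (partly) wet.
#' @param seed RNG seed.
#' @return data.frame `bird_id`, `timestamp` (POSIXct UTC), `wet_count`.
#' @export
simulate_immersion <- function(track, p_wet = 0.4, seed = 1) {
  pos <- track$positions
  if (is.null(pos) || nrow(pos) == 0L) stop("track with no positions")
  set.seed(seed)
  t0 <- as.POSIXct(paste(min(pos$date), "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(max(pos$date), "23:50:00"), tz = "UTC")
  ts <- seq(t0, t1, by = 600)
  day <- as.Date(ts)
  at_colony <- day < track$departure | day >= track$arrival
  wet <- integer(length(ts))
  sea <- !at_colony
  is_wet <- sea & stats::runif(length(ts)) < p_wet
  wet[is_wet] <- sample(1:200, sum(is_wet), replace = TRUE)
  # guarantee at least one wet block per at-sea day
  for (d in unique(day[sea])) {
    idx <- which(day == d & sea)
    if (all(wet[idx] == 0)) wet[sample(idx, 1)] <- sample(1:200, 1)
  }
  data.frame(bird_id = track$bird_id, timestamp = ts, wet_count = wet,
             stringsAsFactors = FALSE)
}

#' Simulate feather isotope values for tracked birds
#'
#' Draws one P1, one S8 and one R6 measurement per bird from the bivariate
#' normal distribution of the bird's class (its non-breeding area by
#' default).
#'
#' @param tracks list of tracks from [simulate_tracks()].
#' @param params class parameter table, see [make_default_isotope_params()].
#' @param label_by draw classes by "area" (default) or "colony".
#' @param feathers feather codes to draw.
#' @param seed RNG seed.
#' @return data.frame `bird_id`, `colony`, `area`, `feather`, `d15N`,
#'   `d13C`, `source`.
#' @export
simulate_feathers <- function(tracks, params = make_default_isotope_params(),
                              label_by = c("area", "colony"),
                              feathers = c("P1", "S8", "R6"), seed = 1) {
  label_by <- match.arg(label_by)
  set.seed(seed)
  p <- params[params$label_by == label_by, ]
  rows <- lapply(tracks, function(tr) {
    lab <- if (label_by == "area") tr$area else tr$colony
    per_feather <- lapply(feathers, function(f) {
      pr <- p[p$feather == f & p$label == lab, ]
      if (nrow(pr) != 1L)
        stop("missing class parameters for feather ", f, ", label ", lab)
      S <- matrix(c(pr$sd_d15N^2,
                    pr$correlation * pr$sd_d15N * pr$sd_d13C,
                    pr$correlation * pr$sd_d15N * pr$sd_d13C,
                    pr$sd_d13C^2), 2, 2)
      x <- MASS::mvrnorm(1, c(pr$mean_d15N, pr$mean_d13C), S)
      data.frame(bird_id = tr$bird_id, colony = tr$colony, area = tr$area,
                 feather = f, d15N = x[1], d13C = x[2], source = "tracked",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_feather)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate non-breeding centroids directly
#'
#' Draws per-bird non-breeding centroids as Gaussian clouds around the two
#' area centres, bypassing the track/geolocation chain. Used for clustering
#' and isoscape experiments at the cohort scale of the study design (86
#' bird-years, about 65 Central and 21 South).
#'
#' @param n_central,n_south cloud sizes.
#' @param sd_deg isotropic cloud SD, degrees (default 2, of the order of
#'   geolocation error).
#' @param areas area table; cloud centres are the box midpoints.
#' @param seed RNG seed.
#' @return data.frame `bird_id`, `area`, `lon`, `lat`.
#' @export
simulate_centroids <- function(n_central = 65, n_south = 21, sd_deg = 2,
                               areas = make_default_areas(), seed = 1) {
  set.seed(seed)
  ctr <- cbind((areas$lon_min + areas$lon_max) / 2,
               (areas$lat_min + areas$lat_max) / 2)
  n <- c(n_central, n_south)
  out <- do.call(rbind, lapply(1:2, function(a) {
    data.frame(area = areas$name[a],
               lon = stats::rnorm(n[a], ctr[a, 1], sd_deg),
               lat = stats::rnorm(n[a], ctr[a, 2], sd_deg),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(bird_id = sprintf("bird%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
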
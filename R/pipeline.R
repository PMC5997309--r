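#' Default analysis configuration
#'
#' All stage parameters with their standard settings: light threshold 20,
#' minimum dark period 4 h, equinox window 20 days, 95th-percentile speed
#' filter, 5% isopleth centroids, candidate cluster numbers 2..10, 70/30
#' train/test split, spherical variogram kriging with a 4-degree buffer
#' mask. Any entry can be overridden, none is changed silently.
#'
#' @param ... named overrides of top-level entries (nested lists replaced
#'   wholesale).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = list(n_birds = 24, area_mix = 21 / 86, year = 2012,
                    sun_elevation = -3, twilight_noise_sd = 2,
                    max_speed_km = 700),
    geolocate = list(threshold = 20, sun_elevation = -3, min_dark = 4,
                     equinox_window = 20, speed_percentile = 95,
                     colony_radius_km = 200, d_days = 3),
    cluster = list(isopleth = 5, k_range = 2:10, kde_cell = 0.25),
    assign = list(train_frac = 0.70, feathers = c("S8", "R6")),
    isoscape = list(grid_cell = 1, buffer_deg = 4, n_lags = 12)
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

#' Validate analysis input tables
#'
#' Schema and range checks for the CSV-shaped tables the pipeline consumes.
#' Violations are reported, never thrown.
#'
#' @param feathers optional feather table (`bird_id`, `feather`, `d15N`,
#'   `d13C`).
#' @param twilights optional twilight table (`bird_id`, `date`, `dawn`,
#'   `dusk`).
#' @param centroids optional centroid table (`bird_id`, `lon`, `lat`).
#' @return data.frame `table`, `check`, `message` (zero rows when clean).
#' @export
validate_inputs <- function(feathers = NULL, twilights = NULL,
                            centroids = NULL) {
  bad <- list()
  note <- function(tb, ck, msg)
    bad[[length(bad) + 1L]] <<- data.frame(table = tb, check = ck,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  if (!is.null(feathers)) {
    need <- c("bird_id", "feather", "d15N", "d13C")
    miss <- setdiff(need, names(feathers))
    if (length(miss)) note("feathers", "columns",
                           paste("missing:", paste(miss, collapse = ", ")))
    else {
      codes <- c("P1", "P3", "P5", "P7", "P10", "S1", "S8", "S12", "R6")
      badc <- setdiff(unique(feathers$feather), codes)
      if (length(badc)) note("feathers", "feather_code",
                             paste("invalid:", paste(badc, collapse = ", ")))
      if (any(feathers$d13C > 0))
        note("feathers", "d13C_sign",
             "positive d13C values; marine feathers are negative vs VPDB")
      if (any(abs(feathers$d15N) > 50) || any(abs(feathers$d13C) > 50))
        note("feathers", "range", "delta values outside plausible per-mil range")
    }
  }
  if (!is.null(twilights)) {
    need <- c("bird_id", "date", "dawn", "dusk")
    miss <- setdiff(need, names(twilights))
    if (length(miss)) note("twilights", "columns",
                           paste("missing:", paste(miss, collapse = ", ")))
    else {
      ok <- !is.na(twilights$dawn) & !is.na(twilights$dusk)
      if (any(twilights$dusk[ok] <= twilights$dawn[ok]))
        note("twilights", "order", "dusk not after dawn")
    }
  }
  if (!is.null(centroids)) {
    need <- c("lon", "lat")
    miss <- setdiff(need, names(centroids))
    if (length(miss)) note("centroids", "columns",
                           paste("missing:", paste(miss, collapse = ", ")))
    else if (any(abs(centroids$lat) > 90) || any(abs(centroids$lon) > 180))
      note("centroids", "range", "coordinates outside valid degrees")
  }
  if (length(bad) == 0L)
    return(data.frame(table = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

#' Run the full analysis chain on synthetic data
#'
#' simulate -> geolocate -> cluster -> assign -> isoscape, in order, as a
#' pure function of the configuration. Outputs are written as CSV (and an
#' ESRI ASCII raster per isoscape) under `out_dir`; a manifest records
#' stage status, wall time and file digests, so identical configurations
#' reproduce identical digests.
#'
#' @param config configuration from [default_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   c("simulate","geolocate","cluster","assign","isoscape").
#' @return manifest list: `config`, per-stage `status`, `files` (named md5
#'   digests), `elapsed_s`, and in-memory `results`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "geolocate", "cluster",
                                    "assign", "isoscape")) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(); status <- list(); files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[name] <<- unname(tools::md5sum(path))
  }

  if ("simulate" %in% stages) {
    sc <- config$simulate
    tracks <- simulate_tracks(n_birds = sc$n_birds, area_mix = sc$area_mix,
                              year = sc$year, max_speed_km = sc$max_speed_km,
                              seed = config$seed)
    res$tracks <- tracks
    res$twilights <- do.call(rbind, lapply(seq_along(tracks), function(i)
      simulate_twilights(tracks[[i]], sun_elevation = sc$sun_elevation,
                         noise_sd = sc$twilight_noise_sd,
                         seed = config$seed + i)))
    res$immersion <- lapply(seq_along(tracks), function(i)
      simulate_immersion(tracks[[i]], seed = config$seed + i))
    names(res$immersion) <- vapply(tracks, `[[`, character(1), "bird_id")
    res$feathers <- simulate_feathers(tracks, seed = config$seed + 1000L)
    put(res$twilights, "twilights.csv")
    put(res$feathers, "feathers.csv")
    put(data.frame(bird_id = vapply(tracks, `[[`, character(1), "bird_id"),
                   colony = vapply(tracks, `[[`, character(1), "colony"),
                   area = vapply(tracks, `[[`, character(1), "area"),
                   departure = vapply(tracks, function(t) as.character(t$departure), character(1)),
                   arrival = vapply(tracks, function(t) as.character(t$arrival), character(1))),
        "truth.csv")
    status$simulate <- "ok"
  }

  if ("geolocate" %in% stages) {
    if (is.null(res$twilights))
      stop("geolocate needs twilights; run the simulate stage first")
    gc <- config$geolocate
    by_bird <- split(res$twilights, res$twilights$bird_id)
    pos_list <- lapply(by_bird, function(tw) {
      tw <- filter_transitions(tw, min_dark = gc$min_dark,
                               equinox_window = gc$equinox_window)
      pos <- positions_from_twilights(tw[, setdiff(names(tw), "flags")],
                                      sun_elevation = gc$sun_elevation)
      pos$flags <- ifelse(nzchar(tw$flags),
                          paste(pos$flags, tw$flags, sep = ";"), pos$flags)
      pos$flags <- sub("^;", "", pos$flags)
      pos
    })
    thr <- cohort_speed_threshold(pos_list, gc$speed_percentile)
    pos_list <- lapply(pos_list, function(p)
      speed_filter(p, threshold_kmh = thr))
    res$positions <- do.call(rbind, pos_list)
    rownames(res$positions) <- NULL
    colonies <- make_default_colonies()
    res$phenology <- do.call(rbind, lapply(res$tracks, function(tr) {
      col <- colonies[colonies$name == tr$colony, ]
      p <- pos_list[[tr$bird_id]]
      w <- nonbreeding_window(p, res$immersion[[tr$bird_id]],
                              colony_lon = col$lon, colony_lat = col$lat,
                              radius_km = gc$colony_radius_km,
                              d_days = gc$d_days)
      data.frame(bird_id = tr$bird_id, resident = w$resident,
                 departure = as.character(w$departure),
                 arrival = as.character(w$arrival),
                 arrival_method = w$arrival_method, stringsAsFactors = FALSE)
    }))
    put(res$positions, "positions.csv")
    put(res$phenology, "phenology.csv")
    status$geolocate <- "ok"
  }

  if ("cluster" %in% stages) {
    if (is.null(res$positions))
      stop("cluster needs positions; run the geolocate stage first")
    cc <- config$cluster
    cents <- lapply(res$tracks, function(tr) {
      p <- res$positions[res$positions$bird_id == tr$bird_id, ]
      ph <- res$phenology[res$phenology$bird_id == tr$bird_id, ]
      if (isTRUE(ph$resident)) return(NULL)
      dep <- as.Date(ph$departure)
      arr <- if (is.na(ph$arrival)) max(p$date) + 1 else as.Date(ph$arrival)
      p <- p[which(!is.na(p$lat) & !nzchar(p$flags) &
                     p$date >= dep & p$date < arr), ]
      if (nrow(p) < 5L) return(NULL)
      ud <- kde_ud(p, cell = cc$kde_cell)
      ct <- isopleth_centroid(ud, level = cc$isopleth)
      data.frame(bird_id = tr$bird_id, area = tr$area,
                 lon = ct["lon"], lat = ct["lat"], stringsAsFactors = FALSE)
    })
    res$centroids <- do.call(rbind, cents)
    rownames(res$centroids) <- NULL
    d <- distance_matrix(res$centroids)
    res$clustering <- select_k(d, cc$k_range)
    res$centroids$cluster <- res$clustering$labels
    put(res$centroids, "centroids.csv")
    jsonlite::write_json(
      list(k = res$clustering$k,
           avg_silhouette = res$clustering$avg_silhouette,
           profile = res$clustering$profile,
           medoids = res$clustering$medoids),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    files["clusters.json"] <- unname(tools::md5sum(file.path(out_dir, "clusters.json")))
    status$cluster <- "ok"
  }

  if ("assign" %in% stages) {
    if (is.null(res$feathers))
      stop("assign needs feathers; run the simulate stage (or supply feathers.csv) first")
    ac <- config$assign
    res$assignment <- lapply(ac$feathers, function(f) {
      fx <- res$feathers[res$feathers$feather == f, ]
      sp <- split_train_test(fx, label_by = "area",
                             train_frac = ac$train_frac, seed = config$seed)
      model <- fit_lda(sp$train, label_by = "area")
      list(feather = f, model = model,
           rates = classification_rates(model, sp$train, sp$test,
                                        label_by = "area"))
    })
    names(res$assignment) <- ac$feathers
    rates <- do.call(rbind, lapply(res$assignment, function(a)
      cbind(feather = a$feather, a$rates)))
    put(rates, "classification_rates.csv")
    status$assign <- "ok"
  }

  if ("isoscape" %in% stages) {
    if (is.null(res$centroids) || is.null(res$feathers))
      stop("isoscape needs centroids and feathers; run cluster and simulate first")
    ic <- config$isoscape
    res$isoscapes <- list()
    for (f in config$assign$feathers) for (iso in c("d15N", "d13C")) {
      fx <- res$feathers[res$feathers$feather == f, ]
      pts <- merge(res$centroids[, c("bird_id", "lon", "lat")],
                   fx[, c("bird_id", iso)], by = "bird_id")
      names(pts)[4] <- "value"
      vg <- empirical_variogram(pts, n_lags = ic$n_lags)
      vm <- fit_spherical(vg)
      grid <- list(lon = seq(floor(min(pts$lon)) - ic$buffer_deg,
                             ceiling(max(pts$lon)) + ic$buffer_deg,
                             by = ic$grid_cell),
                   lat = seq(floor(min(pts$lat)) - ic$buffer_deg,
                             ceiling(max(pts$lat)) + ic$buffer_deg,
                             by = ic$grid_cell))
      kg <- suppressWarnings(krige(pts, vm, grid))
      msk <- buffer_mask(pts, grid, ic$buffer_deg)
      nm <- paste0("isoscape_", f, "_", iso)
      res$isoscapes[[nm]] <- list(grid = kg, mask = msk, variogram = vm)
      fp <- file.path(out_dir, paste0(nm, ".asc"))
      write_esri_ascii(kg, fp, mask = msk)
      files[basename(fp)] <- unname(tools::md5sum(fp))
    }
    status$isoscape <- "ok"
  }

  list(config = config, status = status, files = files,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
       results = res)
}
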
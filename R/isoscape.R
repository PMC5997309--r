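#' Empirical semivariogram
#'
#' gamma(h) = mean of 0.5 * (z_i - z_j)^2 over point pairs whose separation
#' falls in each distance bin. Distances are planar degrees by default
#' (matching interpolation on geographic coordinates), or haversine km.
#'
#' @param points data.frame with `lon`, `lat`, `value` (>= 5 rows).
#' @param n_lags number of distance bins (default 12).
#' @param max_lag largest separation considered (default: the maximum pair
#'   distance, so that structure between distant point clouds enters the
#'   fit).
#' @param dist "degrees" (planar) or "km" (haversine, R = 6371 km).
#' @return data.frame `h` (bin midpoint), `gamma`, `n_pairs`; attribute
#'   `dist` records the metric.
#' @export
empirical_variogram <- function(points, n_lags = 12, max_lag = NULL,
                                dist = c("degrees", "km")) {
  dist <- match.arg(dist)
  stopifnot(nrow(points) >= 5L)
  D <- .pair_dist(points, dist)
  dv <- D[upper.tri(D)]
  if (all(dv == 0)) stop("all points coincident")
  z <- points$value
  gv <- (0.5 * outer(z, z, "-")^2)[upper.tri(D)]
  if (is.null(max_lag)) max_lag <- max(dv)
  br <- seq(0, max_lag, length.out = n_lags + 1L)
  bin <- cut(dv, br, include.lowest = TRUE)
  keep <- !is.na(bin)
  gm <- tapply(gv[keep], bin[keep], mean)
  np <- tapply(rep(1, sum(keep)), bin[keep], sum)
  out <- data.frame(h = (br[-1L] + br[-length(br)]) / 2,
                    gamma = as.numeric(gm), n_pairs = as.numeric(np))
  out$n_pairs[is.na(out$n_pairs)] <- 0
  out <- out[out$n_pairs > 0 & !is.na(out$gamma), ]
  attr(out, "dist") <- dist
  out
}

.pair_dist <- function(points, dist) {
  p <- cbind(points$lon, points$lat)
  if (dist == "degrees") {
    as.matrix(stats::dist(p))
  } else {
    n <- nrow(p)
    i <- rep(seq_len(n), times = n); j <- rep(seq_len(n), each = n)
    matrix(geosphere::distHaversine(p[i, , drop = FALSE], p[j, , drop = FALSE],
                                    r = 6371000) / 1000, n, n)
  }
}

#' Spherical semivariogram value
#'
#' @param h separation distance(s).
#' @param nugget,psill,range spherical model parameters (nugget, partial
#'   sill, range), all >= 0, range > 0.
#' @return gamma(h); 0 at h = 0, nugget + psill beyond the range.
#' @export
spherical_gamma <- function(h, nugget, psill, range) {
  g <- ifelse(h <= 0, 0,
              ifelse(h >= range, nugget + psill,
                     nugget + psill * (1.5 * h / range - 0.5 * (h / range)^3)))
  g
}

#' Fit a spherical semivariogram by weighted least squares
#'
#' Minimizes sum of n_pairs * (gamma_emp - gamma_model)^2 over nonnegative
#' (nugget, partial sill, range). On failure, falls back to nugget 0,
#' partial sill = mean empirical gamma, range = half the largest lag, with
#' a warning.
#'
#' @param vg lag table from [empirical_variogram()] (>= 3 nonempty lags).
#' @return list of class `variogram_model`: `nugget`, `psill`, `range`,
#'   `model` = "spherical", `converged`.
#' @export
fit_spherical <- function(vg) {
  vg <- vg[vg$n_pairs > 0, ]
  if (nrow(vg) < 3L) stop("need at least 3 nonempty lags")
  obj <- function(p) sum(vg$n_pairs *
                           (vg$gamma - spherical_gamma(vg$h, p[1], p[2], p[3]))^2)
  start <- c(0, max(mean(vg$gamma), 1e-8), max(vg$h) * 0.7)
  fit <- try(stats::optim(start, obj, method = "L-BFGS-B",
                          lower = c(0, 1e-10, max(vg$h) * 1e-3),
                          upper = c(Inf, Inf, max(vg$h) * 10)), silent = TRUE)
  fallback <- inherits(fit, "try-error") || fit$convergence != 0
  if (!fallback) {
    # flat empirical variograms leave the range unidentified
    rel <- stats::sd(vg$gamma) / max(mean(vg$gamma), 1e-12)
    if (rel < 0.05) fallback <- TRUE
  }
  if (fallback) {
    warning("spherical fit did not converge; using fallback parameters")
    p <- c(0, mean(vg$gamma), max(vg$h) / 2)
  } else p <- fit$par
  structure(list(nugget = p[1], psill = p[2], range = p[3],
                 model = "spherical", converged = !fallback),
            class = "variogram_model")
}

#' Ordinary kriging onto a grid
#'
#' Solves the ordinary-kriging system (semivariogram form, with a Lagrange
#' multiplier enforcing weights that sum to 1) once per grid cell, sharing
#' a single factorization of the data-data system. Exactly duplicated
#' locations are averaged with a warning.
#'
#' @param points data.frame `lon`, `lat`, `value` (>= 3 rows).
#' @param variogram a `variogram_model`.
#' @param grid list with numeric vectors `lon`, `lat` (cell centres).
#' @param dist distance metric, "degrees" or "km" (must match the
#'   variogram fit).
#' @return list of class `kriged_grid`: `lon`, `lat`, `pred` and `var`
#'   (matrices, rows = lon), `weights_sum` (same shape; always ~1).
#' @export
krige <- function(points, variogram, grid, dist = c("degrees", "km")) {
  dist <- match.arg(dist)
  stopifnot(inherits(variogram, "variogram_model"), nrow(points) >= 3L)
  key <- paste(points$lon, points$lat)
  if (anyDuplicated(key)) {
    warning("duplicate locations averaged before kriging")
    points <- stats::aggregate(value ~ lon + lat, points, mean)
  }
  n <- nrow(points)
  D <- .pair_dist(points, dist)
  G <- spherical_gamma(D, variogram$nugget, variogram$psill, variogram$range)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ainv <- solve(A)
  gx <- grid$lon; gy <- grid$lat
  cells <- cbind(lon = rep(gx, times = length(gy)),
                 lat = rep(gy, each = length(gx)))
  d0 <- if (dist == "degrees") {
    sqrt(outer(points$lon, cells[, 1], "-")^2 +
           outer(points$lat, cells[, 2], "-")^2)
  } else {
    m <- matrix(NA_real_, n, nrow(cells))
    for (i in seq_len(n))
      m[i, ] <- geosphere::distHaversine(c(points$lon[i], points$lat[i]),
                                         cells, r = 6371000) / 1000
    m
  }
  g0 <- spherical_gamma(d0, variogram$nugget, variogram$psill, variogram$range)
  g0[d0 == 0] <- 0
  sol <- Ainv %*% rbind(g0, 1)          # (n+1) x cells: weights + multiplier
  w <- sol[seq_len(n), , drop = FALSE]
  pred <- drop(crossprod(w, points$value))
  kvar <- colSums(sol * rbind(g0, 1)) - 0  # w'g0 + mu
  structure(list(lon = gx, lat = gy,
                 pred = matrix(pred, length(gx), length(gy)),
                 var = matrix(pmax(kvar, 0), length(gx), length(gy)),
                 weights_sum = matrix(colSums(w), length(gx), length(gy))),
            class = "kriged_grid")
}

#' Buffer mask around centroids
#'
#' A grid cell is unmasked (TRUE) iff it lies within `radius_deg` planar
#' degrees of at least one centroid; the interpolation is only shown inside
#' the union of those buffers.
#'
#' @param centroids data.frame `lon`, `lat` (>= 1 row).
#' @param grid list with `lon`, `lat` vectors.
#' @param radius_deg buffer radius, degrees (default 4).
#' @return logical matrix (rows = lon, cols = lat), TRUE inside the buffer.
#' @export
buffer_mask <- function(centroids, grid, radius_deg = 4) {
  stopifnot(nrow(centroids) >= 1L)
  gx <- grid$lon; gy <- grid$lat
  m <- matrix(FALSE, length(gx), length(gy))
  for (i in seq_len(nrow(centroids))) {
    d2 <- outer((gx - centroids$lon[i])^2, (gy - centroids$lat[i])^2, "+")
    m <- m | (d2 <= radius_deg^2)
  }
  m
}

#' Mollweide projection (forward and inverse)
#'
#' Equal-area pseudocylindrical projection used for rendering; analysis
#' values are untouched. Radius 6371 km; central meridian 0.
#'
#' @param lon,lat coordinates, decimal degrees.
#' @return data.frame `x`, `y` in km.
#' @export
to_mollweide <- function(lon, lat) {
  R <- 6371
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  theta <- phi
  for (i in 1:25) {
    dth <- -(2 * theta + sin(2 * theta) - pi * sin(phi)) /
      (2 + 2 * cos(2 * theta))
    dth[abs(cos(theta)) < 1e-12] <- 0
    theta <- theta + dth
    if (max(abs(dth)) < 1e-13) break
  }
  data.frame(x = R * 2 * sqrt(2) / pi * lam * cos(theta),
             y = R * sqrt(2) * sin(theta))
}

#' @param x,y projected coordinates, km.
#' @rdname to_mollweide
#' @export
from_mollweide <- function(x, y) {
  R <- 6371
  theta <- asin(pmin(1, pmax(-1, y / (R * sqrt(2)))))
  phi <- asin(pmin(1, pmax(-1, (2 * theta + sin(2 * theta)) / pi)))
  lam <- pi * x / (2 * R * sqrt(2) * cos(theta))
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Write a kriged grid as an ESRI ASCII raster
#'
#' Masked cells are written as the nodata value. Cell size must be uniform.
#'
#' @param kg a `kriged_grid`.
#' @param file output path.
#' @param mask optional logical matrix from [buffer_mask()].
#' @param nodata nodata value (default -9999).
#' @return the path, invisibly.
#' @export
write_esri_ascii <- function(kg, file, mask = NULL, nodata = -9999) {
  cs <- unique(round(diff(kg$lon), 10))
  stopifnot(length(cs) == 1L)
  z <- kg$pred
  if (!is.null(mask)) z[!mask] <- NA
  z[is.na(z)] <- nodata
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", length(kg$lon)),
    paste("nrows", length(kg$lat)),
    paste("xllcorner", min(kg$lon) - cs / 2),
    paste("yllcorner", min(kg$lat) - cs / 2),
    paste("cellsize", cs),
    paste("NODATA_value", nodata)), con)
  # rows north to south
  for (j in rev(seq_along(kg$lat)))
    writeLines(paste(signif(z[, j], 7), collapse = " "), con)
  invisible(file)
}
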
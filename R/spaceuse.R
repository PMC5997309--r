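#' Kernel utilization distribution on a lon/lat grid
#'
#' Bivariate Gaussian kernel density with a single isotropic bandwidth,
#' evaluated on a regular geographic grid and normalized so that the cell
#' masses sum to 1. The reference bandwidth `"href"` is
#' sqrt(0.5 * (var(lon) + var(lat))) * n^(-1/6).
#'
#' @param positions data.frame with `lon`, `lat` (>= 5 rows).
#' @param bandwidth `"href"` (default) or a numeric bandwidth in degrees.
#' @param cell grid cell size, degrees (default 0.25).
#' @param pad grid padding beyond the data range, in bandwidths (default 3).
#' @return object of class `ud_grid`: list with `lon`, `lat` (cell-centre
#'   vectors), `mass` (matrix, rows = lon, cols = lat, sums to 1),
#'   `bandwidth`, `cell`.
#' @export
kde_ud <- function(positions, bandwidth = "href", cell = 0.25, pad = 3) {
  x <- positions$lon; y <- positions$lat
  n <- length(x)
  if (n < 5L) stop("need at least 5 positions for a utilization distribution")
  h <- if (identical(bandwidth, "href")) {
    sqrt(0.5 * (stats::var(x) + stats::var(y))) * n^(-1 / 6)
  } else as.numeric(bandwidth)
  stopifnot(h > 0)
  gx <- seq(min(x) - pad * h, max(x) + pad * h, by = cell)
  gy <- seq(min(y) - pad * h, max(y) + pad * h, by = cell)
  # density as a mean of Gaussian kernels, via outer-product accumulation
  dx <- outer(gx, x, "-") / h   # |gx| x n
  dy <- outer(gy, y, "-") / h
  kx <- exp(-dx^2 / 2)
  ky <- exp(-dy^2 / 2)
  dens <- kx %*% t(ky) / (n * 2 * pi * h^2)
  mass <- dens * cell^2
  mass <- mass / sum(mass)
  structure(list(lon = gx, lat = gy, mass = mass, bandwidth = h, cell = cell),
            class = "ud_grid")
}

#' Centroid of a utilization-distribution isopleth
#'
#' Selects the highest-density cells whose cumulative mass first reaches
#' `level` percent (the smallest-area region holding that mass) and returns
#' their density-weighted centroid. `level = 5` gives the core-use centroid.
#'
#' @param ud a `ud_grid` from [kde_ud()].
#' @param level isopleth level, percent in (0, 100).
#' @return named numeric `c(lon, lat)`.
#' @export
isopleth_centroid <- function(ud, level = 5) {
  stopifnot(inherits(ud, "ud_grid"), level > 0, level < 100)
  m <- ud$mass
  if (sum(m) <= 0) stop("empty utilization distribution")
  o <- order(m, decreasing = TRUE)
  cum <- cumsum(m[o])
  k <- which(cum >= level / 100)[1L]
  sel <- o[seq_len(k)]
  w <- m[sel] / sum(m[sel])
  ij <- arrayInd(sel, dim(m))
  c(lon = sum(w * ud$lon[ij[, 1L]]), lat = sum(w * ud$lat[ij[, 2L]]))
}

#' Great-circle distance matrix between centroids
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param centroids data.frame with `lon`, `lat` (>= 2 rows).
#' @return symmetric matrix of distances, km, zero diagonal.
#' @export
distance_matrix <- function(centroids) {
  stopifnot(nrow(centroids) >= 2L,
            all(abs(centroids$lat) <= 90), all(abs(centroids$lon) <= 360))
  p <- cbind(centroids$lon, centroids$lat)
  n <- nrow(p)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  d <- geosphere::distHaversine(p[i, , drop = FALSE], p[j, , drop = FALSE],
                                r = 6371000)
  matrix(d / 1000, n, n)
}

#' Partitioning around medoids on a distance matrix
#'
#' k-medoids clustering (BUILD + SWAP) of centroids from their pairwise
#' distances, with the average silhouette width of the partition.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of clusters, 2 <= k < n.
#' @return object of class `area_clustering`: list with `k`, `labels`,
#'   `medoids` (indices), `cost` (total distance to medoids),
#'   `avg_silhouette`.
#' @export
pam_clusters <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of points")
  if (k < 1L) stop("k must be at least 1")
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  labels <- unname(fit$clustering)
  medoids <- as.integer(fit$id.med)
  cost <- sum(d[cbind(seq_len(n), medoids[labels])])
  structure(list(k = k, labels = labels, medoids = medoids, cost = cost,
                 avg_silhouette = mean_silhouette(d, labels)),
            class = "area_clustering")
}

#' Average silhouette width of a partition
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean distance of i
#' to its own cluster and b(i) the smallest mean distance to another
#' cluster; singletons score 0.
#'
#' @param d distance matrix.
#' @param labels integer cluster labels.
#' @return mean silhouette width, in [-1, 1].
#' @export
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette needs at least 2 clusters")
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)  # singleton
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(ks[ks != labels[i]], function(kk)
      mean(d[i, labels == kk]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Select the number of clusters by silhouette width
#'
#' Runs [pam_clusters()] over `k_range` and returns the partition whose
#' average silhouette width is maximal, with the full silhouette profile.
#'
#' @param d distance matrix.
#' @param k_range candidate cluster numbers (default 2:10).
#' @return `area_clustering` with an extra `profile` element
#'   (data.frame `k`, `avg_silhouette`).
#' @export
select_k <- function(d, k_range = 2:10) {
  d <- as.matrix(d)
  n <- nrow(d)
  k_range <- k_range[k_range < n]
  if (length(k_range) == 0L) stop("too few points for any candidate k")
  fits <- lapply(k_range, function(k) pam_clusters(d, k))
  sil <- vapply(fits, `[[`, numeric(1), "avg_silhouette")
  best <- fits[[which.max(sil)]]
  best$profile <- data.frame(k = k_range, avg_silhouette = sil)
  best
}

#' @export
print.area_clustering <- function(x, ...) {
  cat("k-medoids clustering: k =", x$k,
      sprintf("(avg silhouette %.3f)\n", x$avg_silhouette))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}
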
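# Fixtures built in code, shared across test files.

# One simulated day of square-wave light: dark, a clean dawn ramp, bright
# day, a dusk ramp, dark. 10-min sampling.
square_wave_day <- function(date = as.Date("2012-06-01"),
                            dawn_h = 6, dusk_h = 18, bright = 64) {
  ts <- seq(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"),
            by = 600, length.out = 144)
  h <- as.numeric(difftime(ts, ts[1], units = "hours"))
  light <- ifelse(h < dawn_h | h >= dusk_h, 0, bright)
  data.frame(timestamp = ts, light = light)
}

# A minimal hand-built track data.frame in the positions format.
toy_positions <- function(lon, lat, start = as.Date("2012-11-01")) {
  data.frame(bird_id = "t1", date = start + seq_along(lon) - 1L,
             kind = "midday", lon = lon, lat = lat, flags = "",
             stringsAsFactors = FALSE)
}

# Bivariate sample whose *sample* covariance is exactly S and mean mu.
exact_cov_sample <- function(n, mu = c(0, 0), S = diag(2), seed = 1) {
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu, S, empirical = TRUE)
  colnames(X) <- c("d15N", "d13C")
  X
}

# Exhaustive k = 2 medoid search: minimum total distance over all pairs.
brute_force_pam2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(d[, i], d[, j]))
    if (cost < best) best <- cost
  }
  best
}

# Published classification-function coefficients and class means, used as
# frozen reference values across tests.
ref_means <- list(
  S8 = rbind(CentralAtlantic = c(13.1, -16.3), SouthAtlantic = c(14.6, -16.8)),
  R6 = rbind(CentralAtlantic = c(12.8, -16.5), SouthAtlantic = c(15.0, -17.2))
)
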
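# Shared fixtures built in code. The heavier synthetic bundle is built once
# per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

# Identity calibration curve: mu(t) = t, constant sigma.
identity_curve <- function(span = c(0, 7600), sigma = 1e-6, step = 5) {
  grid <- seq(span[1], span[2], by = step)
  calibration_curve(grid, grid, rep(sigma, length(grid)))
}

# Small 5-knot toy curve with a plateau (constant mu over two knots).
toy_plateau_curve <- function() {
  calibration_curve(cal_bp = c(1000, 1500, 2000, 2500, 3000),
                    mu = c(1100, 1600, 1900, 1900, 2900),
                    sigma = c(15, 20, 25, 25, 30))
}

# Independent brute-force calibration oracle: re-evaluates the stated
# Gaussian formula point by point with its own interpolation loop.
brute_calibrate <- function(age, error, curve, resolution = 1,
                            delta_r = 0, delta_r_error = 0, floor = 1e-5) {
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  w <- numeric(length(grid))
  for (i in seq_along(grid)) {
    mu_i <- approx(curve$cal_bp, curve$mu, xout = grid[i])$y
    sd_i <- sqrt(error^2 +
                   approx(curve$cal_bp, curve$sigma, xout = grid[i])$y^2 +
                   delta_r_error^2)
    w[i] <- exp(-((age - delta_r) - mu_i)^2 / (2 * sd_i^2)) /
      (sd_i * sqrt(2 * pi))
  }
  p <- w / sum(w)
  keep <- p >= floor * max(p)
  list(years = grid[keep], p = p[keep] / sum(p[keep]))
}

# A degenerate single-fit ensemble whose density is known exactly.
flat_ensemble <- function(zone = "coastal", grid = seq(0, 7000, by = 20),
                          n_fits = 1) {
  dens <- rep(1 / (max(grid) - min(grid)), length(grid))
  fits <- matrix(rep(dens, n_fits), nrow = n_fits, byrow = TRUE)
  population_ensemble(zone, grid, fits, bandwidth = 50)
}

# Memoised mid-size synthetic bundle shared across test files.
shared_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- simulate_bundle(
      n_individuals = 600,
      dates_per_zone = c(coastal = 150, "mid-elevation" = 150,
                         highland = 100),
      n_fits = 25, seed = 42, resolution = 5, window_width = 100)
  }
  .fixture_cache$bundle
}

shared_exposures <- function() {
  if (is.null(.fixture_cache$exposures)) {
    b <- shared_bundle()
    ens_c <- lapply(b$ensembles, taphonomic_correct)
    .fixture_cache$exposures <- suppressWarnings(
      build_exposures(b$individuals, b$climate, b$ensembles, ens_c,
                      n_draws = 150, seed = 7))
  }
  .fixture_cache$exposures
}

# Design + response for the shared bundle (d15N, uncorrected KDE).
shared_design <- function() {
  b <- shared_bundle()
  ex <- shared_exposures()
  keep <- !is.na(b$individuals$d15N)
  design <- ex[keep, climate_vars()]
  design$population <- ex$kde_uncorrected[keep]
  list(design = design, response = b$individuals$d15N[keep],
       zone = b$individuals$zone[keep],
       lat = b$individuals$lat[keep], lon = b$individuals$lon[keep],
       years = (b$individuals$date_min[keep] +
                  b$individuals$date_max[keep]) / 2)
}
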
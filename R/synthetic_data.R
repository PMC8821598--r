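## Seeded synthetic-data generator: produces every input the pipeline
## consumes (isotope individuals, radiocarbon dates, calibration curve,
## gridded climate) with known ground-truth structure so that covariate
## recovery and effect ranking can be tested end to end.

#' Synthetic calibration curve
#'
#' A stand-in calibration curve on a 5-year calBP grid: the curve mean is the
#' identity (mu(t) = t) plus a smooth zero-mean wiggle built from four random
#' sinusoids scaled to marginal standard deviation `wiggle_amplitude`; the
#' construction bounds the wiggle by `sqrt(8) * wiggle_amplitude < 3 *
#' wiggle_amplitude` everywhere. With `wiggle_amplitude = 0` the curve is the
#' identity map.
#'
#' @param year_min,year_max Curve span in calendar years BP (min < max).
#' @param wiggle_amplitude Wiggle standard deviation in 14C years.
#' @param seed Optional integer seed.
#' @param step calBP grid step (yr).
#' @param sigma Constant curve 1-sigma uncertainty (14C yr).
#' @return A [calibration_curve].
#' @export
make_calibration_curve <- function(year_min, year_max, wiggle_amplitude = 30,
                                   seed = NULL, step = 5, sigma = 10) {
  if (year_min >= year_max) stop("year_min must be less than year_max")
  if (wiggle_amplitude < 0) stop("wiggle_amplitude must be non-negative")
  grid <- seq(year_min, year_max, by = step)
  wiggle <- 0
  if (wiggle_amplitude > 0) {
    with_seed(seed, {
      k <- 4L
      freq <- stats::runif(k, 1 / 3000, 1 / 300)
      phase <- stats::runif(k, 0, 2 * pi)
      wiggle <- wiggle_amplitude * sqrt(2 / k) *
        rowSums(sin(outer(grid, 2 * pi * freq) +
                      matrix(phase, length(grid), k, byrow = TRUE)))
    })
  }
  calibration_curve(grid, grid + wiggle, rep(sigma, length(grid)))
}

#' Simulate gridded climate fields
#'
#' Each cell's series for each of the four variables is a stationary AR(1)
#' process around a cell-specific mean with smooth latitude/longitude
#' gradients, qualitatively emulating coarse GCM output: slow drifts in time,
#' spatial spread across cells. Precipitation is floored at zero.
#'
#' @param lats,lons Cell-center coordinates (defaults emulate a 2.5-degree
#'   grid over the Central Andes).
#' @param year_range Oldest and youngest step in years BP.
#' @param step Time step in years (default 20).
#' @param ar AR(1) coefficient in [0, 1).
#' @param innovation_sd Named numeric: per-variable innovation standard
#'   deviations (zero gives a constant series).
#' @param seed Optional integer seed.
#' @return A [climate_fields] object with steps descending from old to young.
#' @export
simulate_climate_fields <- function(lats = seq(-20, -5, by = 2.5),
                                    lons = seq(-80, -67.5, by = 2.5),
                                    year_range = c(7000, 140), step = 20,
                                    ar = 0.8,
                                    innovation_sd = c(temp = 0.3,
                                                      temp_seasonality = 6,
                                                      precip = 0.12,
                                                      precip_seasonality = 7),
                                    seed = NULL) {
  if (step <= 0) stop("step must be positive")
  if (length(lats) == 0L || length(lons) == 0L) stop("empty grid")
  steps <- seq(max(year_range), min(year_range), by = -step)
  cells <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  ncell <- nrow(cells)
  nt <- length(steps)
  clat <- cells$lat - mean(lats)
  clon <- cells$lon - mean(lons)
  with_seed(seed, {
    ## Smooth gradients with distinct directions per variable plus an
    ## independent per-cell intercept (local climatology), keeping pairwise
    ## cross-variable correlations of the resulting exposures below the 0.70
    ## collinearity screen as in real GCM-derived covariates.
    base <- list(
      temp = 22 + 0.3 * clat + 0.15 * clon + stats::rnorm(ncell, 0, 0.8),
      temp_seasonality = 120 - 6 * clat + 6 * clon +
        stats::rnorm(ncell, 0, 15),
      precip = pmax(3 + 0.18 * clon - 0.08 * clat +
                      stats::rnorm(ncell, 0, 0.5), 0.2),
      precip_seasonality = 150 - 6 * clon - 4 * clat +
        stats::rnorm(ncell, 0, 18)
    )
    values <- lapply(CLIMATE_VARS, function(v) {
      s <- innovation_sd[[v]]
      mu <- base[[v]]
      m <- matrix(0, ncell, nt)
      if (s == 0) {
        m[] <- mu
      } else {
        m[, 1L] <- mu + stats::rnorm(ncell, 0, s / sqrt(1 - ar^2))
        for (t in seq_len(nt - 1L) + 1L)
          m[, t] <- mu + ar * (m[, t - 1L] - mu) + stats::rnorm(ncell, 0, s)
      }
      if (v %in% c("precip", "precip_seasonality")) m <- pmax(m, 0)
      m
    })
    names(values) <- CLIMATE_VARS
  })
  climate_fields(lats, lons, steps, values)
}

## Zone-consistent random site attributes (elevation, distance to coast).
zone_site_geometry <- function(zone, n) {
  switch(zone,
         "coastal" = data.frame(elevation = stats::runif(n, 5, 340),
                                dist_coast = stats::runif(n, 0.5, 14)),
         "mid-elevation" = data.frame(elevation = stats::runif(n, 400, 3400),
                                      dist_coast = stats::runif(n, 20, 250)),
         "highland" = data.frame(elevation = stats::runif(n, 3550, 4800),
                                 dist_coast = stats::runif(n, 120, 600)))
}

#' Default synthetic population curve
#'
#' A two-bump relative population density over 0-7000 yBP (a large late bump
#' and a smaller mid-Holocene one over a low baseline), with slight per-zone
#' timing differences. Used as the ground-truth demographic history from
#' which synthetic radiocarbon dates are drawn.
#'
#' @param years Calendar year BP grid.
#' @return List with `years` and a named list `density` (one non-negative,
#'   unnormalized density per zone).
#' @export
default_pop_curve <- function(years = seq(0, 7000, by = 10)) {
  shift <- c("coastal" = 0, "mid-elevation" = 250, "highland" = 500)
  density <- lapply(ZONES, function(z) {
    0.6 * stats::dnorm(years, 1200 + shift[[z]], 600) +
      0.4 * stats::dnorm(years, 4200 + shift[[z]], 800) + 2e-5
  })
  names(density) <- ZONES
  list(years = years, density = density)
}

#' Simulate radiocarbon dates from a known population curve
#'
#' Calendar death years are drawn proportional to the zone's population
#' density, converted to conventional 14C ages through the curve mean plus
#' Gaussian measurement noise. Site identifiers follow a heavy-tailed
#' (Zipf-like) size distribution so some sites carry many dates, exercising
#' site binning downstream. A fraction of coastal dates is marked marine with
#' a reservoir offset baked into the measured age.
#'
#' @param pop_curve List as returned by [default_pop_curve] (or with a single
#'   numeric `density` applied to every zone).
#' @param n_per_zone Dates per zone: scalar or named vector over [zones()].
#' @param curve A [calibration_curve].
#' @param error_sd Measurement error (1 sigma, 14C yr); also the reported
#'   error column.
#' @param seed Optional integer seed.
#' @param sites_per_zone Number of distinct sites per zone.
#' @param marine_frac Fraction of coastal dates flagged marine.
#' @param lat_range,lon_range Coordinate ranges for site locations.
#' @return Data frame of dates (lab_id, site_id, coordinates, elevation,
#'   dist_coast, age, error, marine, delta_r, delta_r_error, true_year).
#' @export
simulate_dates <- function(pop_curve, n_per_zone, curve, error_sd = 30,
                           seed = NULL, sites_per_zone = 25,
                           marine_frac = 0.1,
                           lat_range = c(-20, -5), lon_range = c(-80, -67.5)) {
  if (any(n_per_zone <= 0)) stop("n_per_zone must be positive")
  n_per_zone <- if (length(n_per_zone) == 1L)
    stats::setNames(rep(n_per_zone, 3L), ZONES) else n_per_zone[ZONES]
  dens <- pop_curve$density
  if (!is.list(dens)) dens <- stats::setNames(rep(list(dens), 3L), ZONES)
  if (any(vapply(dens, function(d) any(d < 0), logical(1))))
    stop("pop_curve density must be non-negative")
  with_seed(seed, {
    out <- lapply(ZONES, function(z) {
      n <- n_per_zone[[z]]
      years <- sample(pop_curve$years, n, replace = TRUE, prob = dens[[z]])
      sites <- paste0(substr(z, 1, 2), "_site", seq_len(sites_per_zone))
      site <- sample(sites, n, replace = TRUE,
                     prob = 1 / seq_len(sites_per_zone))
      geo <- zone_site_geometry(z, sites_per_zone)
      geo$lat <- stats::runif(sites_per_zone, lat_range[1L], lat_range[2L])
      geo$lon <- stats::runif(sites_per_zone, lon_range[1L], lon_range[2L])
      gi <- match(site, sites)
      marine <- if (z == "coastal")
        stats::runif(n) < marine_frac else rep(FALSE, n)
      delta_r <- ifelse(marine, stats::rnorm(n, 150, 30), 0)
      dr_err <- ifelse(marine, 25, 0)
      mu_t <- stats::approx(curve$cal_bp, curve$mu, xout = years, rule = 2)$y
      age <- mu_t + delta_r + stats::rnorm(n, 0, error_sd)
      data.frame(lab_id = paste0(toupper(substr(z, 1, 2)), "-",
                                 seq_len(n)),
                 site_id = site,
                 lat = geo$lat[gi], lon = geo$lon[gi],
                 elevation = geo$elevation[gi],
                 dist_coast = geo$dist_coast[gi],
                 age = age, error = rep_len(error_sd, n),
                 marine = marine, delta_r = delta_r,
                 delta_r_error = dr_err,
                 true_year = years,
                 stringsAsFactors = FALSE)
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ground truth for the synthetic response function
#'
#' The synthetic isotope response is additive in the (empirically
#' standardized) true covariates plus one climate-by-climate interaction
#' (temperature x precipitation), so that interaction-deducted effect sizes
#' and Friedman's H have something to detect. `effect_shares` give the
#' intended fraction of total response variance carried by each component;
#' the remainder (1 - sum) is the Gaussian noise share realized with standard
#' deviation `noise_sd`.
#'
#' @param effect_shares Named non-negative fractions for `temp`,
#'   `temp_seasonality`, `precip`, `precip_seasonality`, `population`,
#'   `interaction`; sum at most 1. Defaults put 0.75 of the variance on
#'   climate (including the interaction), 0.10 on population and 0.15 on
#'   noise.
#' @param noise_sd Residual standard deviation in per mil.
#' @param total_sd Fallback response scale (per mil) when the noise share or
#'   `noise_sd` is zero.
#' @param baseline_d15N,baseline_d13C Named per-zone intercepts (per mil).
#' @param seed Integer seed recorded with the truth.
#' @return Object of class `ground_truth`.
#' @export
default_truth <- function(effect_shares = c(temp = 0.17,
                                            temp_seasonality = 0.17,
                                            precip = 0.20,
                                            precip_seasonality = 0.16,
                                            population = 0.10,
                                            interaction = 0.05),
                          noise_sd = 1.2, total_sd = 3,
                          baseline_d15N = c("coastal" = 16,
                                            "mid-elevation" = 10,
                                            "highland" = 9.5),
                          baseline_d13C = c("coastal" = -11,
                                            "mid-elevation" = -13,
                                            "highland" = -16),
                          seed = NA_integer_) {
  if (any(effect_shares < 0)) stop("effect_shares must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  s <- sum(effect_shares)
  if (s > 1 + 1e-9) stop("effect_shares must sum to at most 1")
  noise_share <- max(0, 1 - s)
  scale <- if (noise_share > 0 && noise_sd > 0)
    noise_sd / sqrt(noise_share) else total_sd
  structure(list(effect_shares = effect_shares, noise_sd = noise_sd,
                 scale = scale, noise_share = noise_share,
                 baseline_d15N = baseline_d15N,
                 baseline_d13C = baseline_d13C, seed = seed),
            class = "ground_truth")
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate isotope individuals with known covariate structure
#'
#' Each individual receives a true death year, a date window of width
#' `window_width` containing it, a zone-consistent location, and isotope
#' values generated as the truth's response function of the true local
#' climate at the death year and the zone's population proxy at that year,
#' plus Gaussian noise. True covariates are recorded in `true_*` columns for
#' recovery tests. A fraction of individuals receives a direct radiocarbon
#' measurement; small fractions of under-five, out-of-range C:N, and
#' Colonial records are injected to exercise the QC filters.
#'
#' @param n Number of individuals.
#' @param climate A [climate_fields] object.
#' @param pop A [population_ensemble] or named list of ensembles per zone;
#'   the ensemble-mean density is the "true" population covariate.
#' @param truth A `ground_truth` from [default_truth].
#' @param window_width Date window width in years (non-negative).
#' @param seed Optional integer seed.
#' @param curve [calibration_curve] used to synthesize direct 14C ages
#'   (required when `dated_fraction > 0`).
#' @param dated_fraction Fraction of individuals directly 14C dated.
#' @param span Oldest/youngest allowed true death year (yBP).
#' @param zone_probs Sampling probabilities of the three zones.
#' @param sites_per_zone Distinct sites per zone.
#' @param frac_under5,frac_bad_cn,frac_colonial QC-exercising fractions.
#' @param missing_d15N,missing_d13C Fractions with a missing isotope value.
#' @return Data frame of individuals.
#' @export
simulate_individuals <- function(n, climate, pop, truth = default_truth(),
                                 window_width = 200, seed = NULL,
                                 curve = NULL, dated_fraction = 0.09,
                                 span = c(6900, 200),
                                 zone_probs = c(0.4, 0.4, 0.2),
                                 sites_per_zone = 15,
                                 frac_under5 = 0.02, frac_bad_cn = 0.02,
                                 frac_colonial = 0.01,
                                 missing_d15N = 0.02, missing_d13C = 0.01) {
  if (window_width < 0) stop("window_width must be non-negative")
  if (dated_fraction > 0 && is.null(curve))
    stop("curve required when dated_fraction > 0")
  if (inherits(pop, "population_ensemble"))
    pop <- stats::setNames(rep(list(pop), 3L), ZONES)
  if (!all(ZONES %in% names(pop)))
    stop("pop must cover every zone")
  with_seed(seed, {
    zone <- sample(ZONES, n, replace = TRUE, prob = zone_probs)
    sites <- lapply(ZONES, function(z) {
      g <- zone_site_geometry(z, sites_per_zone)
      g$lat <- stats::runif(sites_per_zone, min(climate$lats),
                            max(climate$lats))
      g$lon <- stats::runif(sites_per_zone, min(climate$lons),
                            max(climate$lons))
      g$site_id <- paste0("ind_", substr(z, 1, 2), "_s",
                          seq_len(sites_per_zone))
      g
    })
    names(sites) <- ZONES
    site_idx <- sample.int(sites_per_zone, n, replace = TRUE)
    geo <- do.call(rbind, lapply(seq_len(n), function(i)
      sites[[zone[i]]][site_idx[i], ]))

    true_year <- round(stats::runif(n, min(span), max(span)))
    offset <- floor(stats::runif(n, 0, window_width + 1))
    date_min <- pmax(true_year - offset, 0)
    date_max <- pmin(date_min + window_width, 7000)
    date_min <- pmin(date_min, true_year)

    cell <- nearest_cell(climate, geo$lat, geo$lon)
    step_idx <- nearest_index_descending(true_year, climate$steps)
    covars <- vapply(CLIMATE_VARS, function(v)
      climate$values[[v]][cbind(cell, step_idx)], numeric(n))
    covars <- as.data.frame(covars)

    pop_val <- numeric(n)
    for (z in ZONES) {
      idx <- which(zone == z)
      if (!length(idx)) next
      ens <- pop[[z]]
      mean_fit <- colMeans(ens$fits)
      yi <- nearest_index_ascending(true_year[idx], ens$years)
      pop_val[idx] <- mean_fit[yi]
    }

    zs <- as.data.frame(lapply(covars, standardize))
    zs$population <- standardize(pop_val)
    zs$interaction <- standardize(zs$temp * zs$precip)
    shares <- truth$effect_shares
    comp_names <- names(shares)
    signal <- as.matrix(zs[, comp_names, drop = FALSE]) %*%
      (sqrt(shares) * truth$scale)
    d15N <- truth$baseline_d15N[zone] + as.numeric(signal) +
      stats::rnorm(n, 0, truth$noise_sd)
    d13C <- truth$baseline_d13C[zone] + as.numeric(signal) +
      stats::rnorm(n, 0, truth$noise_sd)

    dated <- stats::runif(n) < dated_fraction
    c14_age <- rep(NA_real_, n)
    c14_error <- rep(NA_real_, n)
    if (any(dated)) {
      mu_t <- stats::approx(curve$cal_bp, curve$mu, xout = true_year[dated],
                            rule = 2)$y
      c14_error[dated] <- 25
      c14_age[dated] <- mu_t + stats::rnorm(sum(dated), 0, 25)
    }

    age_class <- as.character(round(stats::runif(n, 18, 60)))
    under5 <- stats::runif(n) < frac_under5
    age_class[under5] <- sample(c("2", "infant", "4"), sum(under5),
                                replace = TRUE)
    cn_ratio <- round(stats::runif(n, 2.95, 3.5), 2)
    bad_cn <- stats::runif(n) < frac_bad_cn
    cn_ratio[bad_cn] <- round(stats::runif(sum(bad_cn), 2.0, 2.55), 2)
    study_val <- stats::runif(n) < 0.05
    cn_ratio[study_val] <- NA_real_
    period <- rep("Precolonial", n)
    period[stats::runif(n) < frac_colonial] <- "Colonial"
    d15N[stats::runif(n) < missing_d15N] <- NA_real_
    d13C[stats::runif(n) < missing_d13C] <- NA_real_

    data.frame(id = paste0("IND-", seq_len(n)),
               site_id = geo$site_id,
               lat = geo$lat, lon = geo$lon,
               elevation = geo$elevation, dist_coast = geo$dist_coast,
               d13C = d13C, d15N = d15N, cn_ratio = cn_ratio,
               author_accepted = FALSE, study_validated = study_val,
               age_class = age_class, period = period,
               date_min = date_min, date_max = date_max,
               c14_age = c14_age, c14_error = c14_error,
               zone = zone, true_year = true_year,
               true_temp = covars$temp,
               true_temp_seasonality = covars$temp_seasonality,
               true_precip = covars$precip,
               true_precip_seasonality = covars$precip_seasonality,
               true_population = pop_val,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic bundle
#'
#' Runs the generator end to end: calibration curve, climate fields,
#' two-bump population curve, radiocarbon dates, date QC + calibration +
#' binning + per-zone composite KDEs, then individuals whose isotope values
#' are a known function of their true climate and population covariates.
#' Defaults reproduce the study's scale (1965 individuals; 1304/1843/810
#' dates per zone; 1000 KDE fits); tests and demos pass smaller values.
#'
#' @param n_individuals Number of individuals.
#' @param dates_per_zone Named or unnamed vector of dates per zone.
#' @param n_fits KDE ensemble size.
#' @param bandwidth KDE bandwidth (yr).
#' @param wiggle_amplitude Curve wiggle (14C yr).
#' @param error_sd Date measurement error (14C yr).
#' @param truth A `ground_truth`.
#' @param window_width Individual date window width (yr).
#' @param resolution Calibration grid step (yr).
#' @param kde_grid Ascending calendar grid for the KDEs.
#' @param seed Master seed; sub-seeds are derived per component.
#' @param ... Passed on to [simulate_individuals].
#' @return List (class `synthetic_bundle`): `individuals`, `dates`, `curve`,
#'   `climate`, `truth`, plus `ensembles` (per-zone uncorrected
#'   [population_ensemble]s), `pop_curve`, `bins` and calibrated
#'   `densities`.
#' @export
simulate_bundle <- function(n_individuals = 1965,
                            dates_per_zone = c(coastal = 1304,
                                               "mid-elevation" = 1843,
                                               highland = 810),
                            n_fits = 1000, bandwidth = 50,
                            wiggle_amplitude = 30, error_sd = 30,
                            truth = default_truth(), window_width = 200,
                            resolution = 5,
                            kde_grid = seq(0, 7000, by = 20), seed = 1, ...) {
  truth$seed <- seed
  curve <- make_calibration_curve(0, 7600, wiggle_amplitude,
                                  seed = stage_seed(seed, "curve"))
  climate <- simulate_climate_fields(seed = stage_seed(seed, "climate"))
  pop_curve <- default_pop_curve()
  dates <- simulate_dates(pop_curve, dates_per_zone, curve,
                          error_sd = error_sd,
                          seed = stage_seed(seed, "dates"))
  qc <- qc_dates(dates)
  densities <- lapply(seq_len(nrow(qc$dates)), function(i)
    calibrate(qc$dates[i, ], curve, resolution = resolution))
  names(densities) <- qc$dates$lab_id
  qc$dates$median_year <- vapply(densities, density_median, numeric(1))
  qc$dates$zone <- classify_zone(qc$dates$elevation, qc$dates$dist_coast)
  bins <- bin_dates(qc$dates)
  ensembles <- lapply(ZONES, function(z) {
    idx <- which(qc$dates$zone == z)
    composite_kde(densities[idx], bins[idx, , drop = FALSE],
                  n_fits = n_fits, bandwidth = bandwidth, grid = kde_grid,
                  seed = stage_seed(seed, paste0("kde_", z)), zone = z)
  })
  names(ensembles) <- ZONES
  individuals <- simulate_individuals(n_individuals, climate, ensembles,
                                      truth, window_width = window_width,
                                      curve = curve,
                                      seed = stage_seed(seed, "individuals"),
                                      ...)
  structure(list(individuals = individuals, dates = dates, curve = curve,
                 climate = climate, truth = truth, ensembles = ensembles,
                 pop_curve = pop_curve, bins = bins, densities = densities),
            class = "synthetic_bundle")
}

#' Write / read the synthetic bundle's input files
#'
#' Persists exactly the files the pipeline consumes: `individuals.csv`,
#' `dates.csv`, `curve.14c` (3-column calBP / 14C age / 1 sigma),
#' `climate_long.csv` and `truth.json`. All CSVs have a header row, UTF-8,
#' '.' decimal.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if absent).
#' @return `read_bundle` returns a list with `individuals`, `dates`, `curve`,
#'   `climate` and `truth`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_individuals(bundle$individuals, file.path(dir, "individuals.csv"))
  utils::write.csv(bundle$dates, file.path(dir, "dates.csv"),
                   row.names = FALSE)
  write_calcurve(bundle$curve, file.path(dir, "curve.14c"))
  write_climate(bundle$climate, file.path(dir, "climate_long.csv"))
  tr <- unclass(bundle$truth)
  # named atomic vectors lose names in JSON arrays; store as objects
  tr$effect_shares <- as.list(tr$effect_shares)
  tr$baseline_d15N <- as.list(tr$baseline_d15N)
  tr$baseline_d13C <- as.list(tr$baseline_d13C)
  write_json_file(tr, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- default_truth(effect_shares = unlist(tr$effect_shares),
                         noise_sd = tr$noise_sd,
                         baseline_d15N = unlist(tr$baseline_d15N),
                         baseline_d13C = unlist(tr$baseline_d13C),
                         seed = tr$seed)
  list(individuals = read_individuals(file.path(dir, "individuals.csv")),
       dates = utils::read.csv(file.path(dir, "dates.csv"),
                               stringsAsFactors = FALSE),
       curve = read_calcurve(file.path(dir, "curve.14c")),
       climate = read_climate(file.path(dir, "climate_long.csv")),
       truth = truth)
}
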
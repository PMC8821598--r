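## Monte-Carlo assignment of lifetime climate and population covariates to
## individuals, plus the per-cell climate z-score series.

#' Sample calendar years from an individual's date window
#'
#' Directly dated individuals are sampled from their calibrated calendar
#' density restricted to the window; all others are sampled uniformly over
#' the (integer-year) window. The window convention is `date_min <=
#' date_max` in years BP, the larger bound being the older edge.
#'
#' @param ind List or one-row data frame with `date_min` and `date_max`, and
#'   optionally `density` (a [calendar_density] for directly dated
#'   individuals).
#' @param n_draws Number of draws (study default 10,000).
#' @param seed Optional integer seed.
#' @return Numeric vector of calendar years BP.
#' @export
window_sampler <- function(ind, n_draws = 10000, seed = NULL) {
  lo <- as.numeric(ind$date_min)
  hi <- as.numeric(ind$date_max)
  if (is.na(lo) || is.na(hi) || lo > hi) stop("date window is empty")
  d <- ind$density
  if (inherits(d, "calendar_density")) {
    keep <- d$years >= lo & d$years <= hi
    if (!any(keep) || sum(d$p[keep]) <= 0)
      stop(sprintf("calibrated density has no mass inside window [%g, %g]",
                   lo, hi))
    d <- calendar_density(d$years[keep], d$p[keep] / sum(d$p[keep]))
    sample_years(d, n_draws, seed = seed)
  } else {
    with_seed(seed, lo + sample.int(hi - lo + 1L, n_draws,
                                    replace = TRUE) - 1L)
  }
}

## Clamp a window to the analysis span, warning when truncation occurs.
clamp_window <- function(date_min, date_max, span = c(140, 7000)) {
  lo <- max(date_min, span[1L])
  hi <- min(date_max, span[2L])
  if (lo > hi) { lo <- span[1L]; hi <- span[1L] }
  truncated <- lo != date_min || hi != date_max
  list(date_min = lo, date_max = hi, truncated = truncated)
}

#' Mean climate exposure over sampled years
#'
#' Each sampled year is mapped to the nearest 20-year step (ties toward the
#' younger step) of the grid cell nearest the individual's coordinates; the
#' arithmetic mean of each variable over the draws is returned.
#'
#' @param fields A [climate_fields] object.
#' @param lat,lon Individual coordinates (must lie inside the grid hull).
#' @param years Sampled calendar years BP (from [window_sampler]).
#' @return Named numeric of the four per-variable means.
#' @export
assign_climate <- function(fields, lat, lon, years) {
  cell <- nearest_cell(fields, lat, lon)
  idx <- nearest_index_descending(years, fields$steps)
  vapply(CLIMATE_VARS, function(v)
    mean(fields$values[[v]][cell, idx]), numeric(1))
}

#' Mean population-proxy exposure over sampled years
#'
#' Per draw, one of the ensemble's KDE fits is chosen uniformly at random,
#' the drawn year is mapped to the nearest grid year, and that fit's density
#' value is retained; the mean over draws is returned. The spread across
#' fits propagates the calibration uncertainty of the demographic
#' reconstruction into the covariate.
#'
#' @param ens A [population_ensemble] covering the window.
#' @param years Sampled calendar years BP.
#' @param seed Optional integer seed (for the fit draws).
#' @return Mean KDE density value.
#' @export
assign_population <- function(ens, years, seed = NULL) {
  if (any(years < min(ens$years) - 10 | years > max(ens$years) + 10))
    stop("window outside ensemble grid")
  with_seed(seed, {
    fit_idx <- sample.int(nrow(ens$fits), length(years), replace = TRUE)
    yi <- nearest_index_ascending(years, ens$years)
    mean(ens$fits[cbind(fit_idx, yi)])
  })
}

#' Build the Monte-Carlo exposure table
#'
#' One row per individual: the mean of each climate variable and of the
#' population proxy (both KDE variants) over `n_draws` weighted samples of
#' the individual's date window. Windows extending beyond the analysis span
#' are truncated with a warning. One set of year draws per individual is
#' shared across covariates (fit indices for the population proxy are drawn
#' independently), which leaves the joint sampling distribution unchanged.
#'
#' @param individuals Data frame with `id`, `zone`, `lat`, `lon`,
#'   `date_min`, `date_max`.
#' @param fields A [climate_fields] object.
#' @param ens_uncorrected,ens_corrected Named lists of per-zone
#'   [population_ensemble]s (corrected variant optional).
#' @param densities Optional named list of [calendar_density] per
#'   individual id (directly dated individuals).
#' @param n_draws Draws per individual (study default 10,000).
#' @param seed Integer seed.
#' @param span Analysis span (youngest, oldest) in years BP.
#' @return Data frame of exposure records.
#' @export
build_exposures <- function(individuals, fields, ens_uncorrected,
                            ens_corrected = NULL, densities = NULL,
                            n_draws = 10000, seed = 1,
                            span = c(140, 7000)) {
  n <- nrow(individuals)
  set.seed(seed)
  any_trunc <- FALSE
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ind <- as.list(individuals[i, ])
    cw <- clamp_window(ind$date_min, ind$date_max, span)
    any_trunc <- any_trunc || cw$truncated
    ind$date_min <- cw$date_min
    ind$date_max <- cw$date_max
    if (!is.null(densities) && !is.null(densities[[ind$id]]))
      ind$density <- densities[[ind$id]]
    years <- tryCatch(window_sampler(ind, n_draws),
                      error = function(e) NULL)
    if (is.null(years)) { # density mass entirely outside clamped window
      ind$density <- NULL
      years <- window_sampler(ind, n_draws)
    }
    clim <- assign_climate(fields, ind$lat, ind$lon, years)
    ens_u <- ens_uncorrected[[ind$zone]]
    kde_u <- assign_population(ens_u, years)
    kde_c <- if (!is.null(ens_corrected))
      assign_population(ens_corrected[[ind$zone]], years) else NA_real_
    rows[[i]] <- data.frame(individual_id = ind$id, zone = ind$zone,
                            t(clim), kde_uncorrected = kde_u,
                            kde_corrected = kde_c, n_draws = n_draws,
                            stringsAsFactors = FALSE)
  }
  if (any_trunc)
    warning("some date windows were truncated to the analysis span ",
            sprintf("[%g, %g] yBP", span[1L], span[2L]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Climate z-score series and central tendency
#'
#' Per cell and variable, the series is standardized over the analysis span
#' ((value - cell mean) / cell sd); a zero-variance cell yields z = 0 with a
#' warning. The central line is a moving average of the cross-cell mean
#' z-score.
#'
#' @param fields A [climate_fields] object.
#' @param smooth_window Moving-average window in steps (odd recommended).
#' @return List with `z` (named list of cell x step matrices) and `central`
#'   (data frame: variable, year_bp, mean_z, smoothed).
#' @export
climate_zscores <- function(fields, smooth_window = 5) {
  if (length(fields$steps) < 2L) stop("need at least two steps")
  z <- lapply(CLIMATE_VARS, function(v) {
    m <- fields$values[[v]]
    mu <- rowMeans(m)
    s <- apply(m, 1L, stats::sd)
    if (any(s == 0)) {
      warning("zero-variance cell(s): z-scores emitted as 0")
      s[s == 0] <- Inf
    }
    (m - mu) / s
  })
  names(z) <- CLIMATE_VARS
  central <- do.call(rbind, lapply(CLIMATE_VARS, function(v) {
    mz <- colMeans(z[[v]])
    sm <- as.numeric(stats::filter(mz, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    data.frame(variable = v, year_bp = fields$steps, mean_z = mz,
               smoothed = sm)
  }))
  list(z = z, central = central)
}
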
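## Dates-as-data population proxies: date QC, site-level binning, composite
## KDE ensembles, and taphonomic correction.

#' Quality-control a radiocarbon date table
#'
#' Applied in order: duplicate lab IDs reduced to the first occurrence; dates
#' older than 15,000 14C yr BP dropped as unlikely to be anthropogenic; dates
#' with 1-sigma errors above 200 yr dropped as unreliable; dates with missing
#' coordinates dropped unless flagged exempt (compilations known to be
#' exclusively coastal can be zoned without coordinates).
#'
#' @param dates Data frame with `lab_id`, `age`, `error`, `lat`, `lon` and
#'   optionally a logical `coastal_exempt` column.
#' @return List with `dates` (retained rows) and `report` (counts per rule).
#' @export
qc_dates <- function(dates) {
  x <- dates
  n_input <- nrow(x)

  dup <- duplicated(x$lab_id)
  x <- x[!dup, , drop = FALSE]

  old <- x$age > 15000
  x <- x[!old, , drop = FALSE]

  bad_err <- x$error > 200
  x <- x[!bad_err, , drop = FALSE]

  exempt <- if (!is.null(x$coastal_exempt)) x$coastal_exempt %in% TRUE
            else rep(FALSE, nrow(x))
  no_coord <- (is.na(x$lat) | is.na(x$lon)) & !exempt
  x <- x[!no_coord, , drop = FALSE]

  list(dates = x,
       report = list(input = n_input,
                     dropped_duplicate = sum(dup),
                     dropped_old = sum(old),
                     dropped_error = sum(bad_err),
                     dropped_no_coords = sum(no_coord),
                     retained = nrow(x)))
}

#' Bin dates within sites by hierarchical clustering
#'
#' Controls for over-representation of intensively dated sites: within each
#' site, dates are clustered on their median calibrated year by agglomerative
#' hierarchical clustering (complete linkage by default) and the dendrogram is
#' cut at `cutoff` years; each cluster becomes one bin.
#'
#' @param dates Data frame with `lab_id`, `site_id` and `median_year`
#'   (median calibrated calendar year BP, see [density_median]).
#' @param cutoff Dendrogram cut height in years (default 200).
#' @param linkage Agglomeration method passed to [stats::hclust].
#' @return Data frame with `lab_id`, `site_id`, `bin_id`, `bin_size`.
#' @export
bin_dates <- function(dates, cutoff = 200, linkage = "complete") {
  stopifnot(!is.null(dates$site_id), !is.null(dates$median_year))
  out <- lapply(split(seq_len(nrow(dates)), dates$site_id), function(idx) {
    site <- dates[idx, , drop = FALSE]
    if (nrow(site) == 1L) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::dist(site$median_year), method = linkage)
      cl <- stats::cutree(hc, h = cutoff)
    }
    data.frame(lab_id = site$lab_id,
               site_id = site$site_id,
               bin_id = paste0(site$site_id[1L], "_", cl),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$bin_size <- as.integer(table(res$bin_id)[res$bin_id])
  res[match(dates$lab_id, res$lab_id), , drop = FALSE]
}

#' Construct a population ensemble object
#'
#' @param zone Elevation zone label.
#' @param years Ascending calendar year BP grid.
#' @param fits Matrix (n_fits x length(years)) of density values; each row
#'   integrates to one over the grid.
#' @param corrected Logical: taphonomically corrected?
#' @param bandwidth KDE bandwidth (yr).
#' @param metadata Optional list (linkage, cutoff, seed, ...).
#' @return Object of class `population_ensemble`.
#' @export
population_ensemble <- function(zone, years, fits, corrected = FALSE,
                                bandwidth = NA_real_, metadata = list()) {
  if (ncol(fits) != length(years)) stop("fits columns must match years")
  if (any(fits < 0)) stop("densities must be non-negative")
  ints <- apply(fits, 1L, function(f) trapz(years, f))
  if (any(abs(ints - 1) > 1e-6))
    stop("each fit must integrate to 1 over the grid")
  structure(list(zone = zone, years = as.numeric(years), fits = fits,
                 corrected = corrected, bandwidth = bandwidth,
                 metadata = metadata),
            class = "population_ensemble")
}

#' @export
print.population_ensemble <- function(x, ...) {
  cat(sprintf(
    "<population_ensemble> zone=%s fits=%d grid=%g-%g yBP bw=%g %s\n",
    x$zone, nrow(x$fits), min(x$years), max(x$years), x$bandwidth,
    if (x$corrected) "(taphonomically corrected)" else "(uncorrected)"))
  invisible(x)
}

#' Composite kernel density estimate of relative population
#'
#' Builds an ensemble of KDE fits expressing calibration uncertainty: for each
#' fit, one calendar year is drawn from every date's calibrated density, each
#' date is weighted by the reciprocal of its site bin size (so intensively
#' dated site phases do not dominate), and a Gaussian KDE with fixed
#' bandwidth is evaluated on the common grid and renormalized to integrate
#' to one.
#'
#' @param densities List of [calendar_density] objects, one per date.
#' @param bins Data frame from [bin_dates] aligned with `densities` (same
#'   order); `bin_size` supplies the weights. `NULL` for unit weights.
#' @param n_fits Number of ensemble fits (study default 1000).
#' @param bandwidth Gaussian kernel standard deviation in years.
#' @param grid Ascending calendar year BP evaluation grid.
#' @param seed Optional integer seed.
#' @param zone Zone label stored on the result.
#' @return A [population_ensemble].
#' @export
composite_kde <- function(densities, bins = NULL, n_fits = 1000,
                          bandwidth = 50, grid = seq(0, 7000, by = 20),
                          seed = NULL, zone = "all") {
  if (length(densities) == 0L) stop("empty date set")
  stopifnot(bandwidth > 0)
  nd <- length(densities)
  w <- if (is.null(bins)) rep(1, nd) else 1 / bins$bin_size
  w <- w / sum(w)
  with_seed(seed, {
    draws <- vapply(densities, sample_years, numeric(n_fits), n = n_fits)
  })
  # draws: n_fits x nd
  fits <- matrix(0, n_fits, length(grid))
  for (f in seq_len(n_fits)) {
    x <- draws[f, ]
    d <- stats::dnorm(outer(x, grid, "-"), sd = bandwidth)  # nd x grid
    dens <- as.numeric(crossprod(w, d))
    fits[f, ] <- dens / trapz(grid, dens)
  }
  population_ensemble(zone, grid, fits, corrected = FALSE,
                      bandwidth = bandwidth,
                      metadata = list(n_dates = nd, seed = seed,
                                      weighting = "1/bin_size"))
}

#' Taphonomic survival model for datable material
#'
#' Global power-law estimate of the number of surviving datable deposits of
#' age t: n(t) = 5,726,442 * (t + 2176.4)^(-1.3925309), a strictly
#' decreasing function of age.
#'
#' @param t Age in calendar years BP.
#' @return Expected surviving count (arbitrary units).
#' @export
surovell_survival <- function(t) {
  5726442 * (t + 2176.4)^(-1.3925309)
}

#' Taphonomically correct a population ensemble
#'
#' Divides each fit pointwise by the relative survival proportion
#' s(t) = n(t)/n(t_ref), with n(t) the [surovell_survival] power law and
#' t_ref the youngest grid year, then renormalizes each fit to integrate to
#' one. Older periods, whose datable material preferentially decayed, are
#' boosted accordingly.
#'
#' @param ens An uncorrected [population_ensemble].
#' @return A corrected [population_ensemble].
#' @export
taphonomic_correct <- function(ens) {
  if (isTRUE(ens$corrected)) stop("ensemble is already taphonomically corrected")
  s <- surovell_survival(ens$years) / surovell_survival(min(ens$years))
  fits <- sweep(ens$fits, 2L, s, "/")
  ints <- apply(fits, 1L, function(f) trapz(ens$years, f))
  fits <- fits / ints
  population_ensemble(ens$zone, ens$years, fits, corrected = TRUE,
                      bandwidth = ens$bandwidth, metadata = ens$metadata)
}

#' Read / write a population ensemble as CSV + JSON metadata
#'
#' The fits matrix is persisted as a CSV (one row per fit, one column per
#' grid year) next to a JSON metadata file carrying zone, bandwidth,
#' corrected flag and provenance.
#'
#' @param ens A [population_ensemble].
#' @param path CSV path; metadata written to `<path>.json`.
#' @export
write_ensemble <- function(ens, path) {
  m <- as.data.frame(ens$fits)
  names(m) <- paste0("y", ens$years)
  utils::write.csv(m, path, row.names = FALSE)
  write_json_file(list(zone = ens$zone, years = ens$years,
                       corrected = ens$corrected, bandwidth = ens$bandwidth,
                       metadata = ens$metadata),
                  paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fits <- as.matrix(utils::read.csv(path))
  dimnames(fits) <- NULL
  population_ensemble(meta$zone, meta$years, fits,
                      corrected = meta$corrected, bandwidth = meta$bandwidth,
                      metadata = as.list(meta$metadata))
}
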
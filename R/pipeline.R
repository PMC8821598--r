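## Staged, seeded pipeline: simulate -> qc -> calibrate -> kde -> assign ->
## trends -> model -> effects -> report. Every stage reads its upstream
## artifacts from the output directory and writes its own, so stages are
## independently re-runnable and a rerun with the same config is
## byte-identical.

#' Pipeline configuration
#'
#' All tunables with their study defaults: 10,000 Monte-Carlo draws per
#' individual, 1000 KDE fits, 10,000 trend-ensemble runs, 100 effect
#' iterations of 100 sampled values, 200-year site-binning cutoff, 0.70
#' collinearity threshold, tenfold cross-validation, 50-year KDE bandwidth.
#' Override any entry via `...`.
#'
#' @param seed Master seed; each stage derives a named sub-seed from it.
#' @param ... Overrides of any default listed above (see the source for the
#'   full set of names).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_individuals = 1965,
    dates_per_zone = c(coastal = 1304, "mid-elevation" = 1843,
                       highland = 810),
    n_draws = 10000,        # MC draws per individual
    n_fits = 1000,          # KDE ensemble size
    n_runs = 10000,         # trend-ensemble GAM runs
    n_iter = 100,           # effect-size iterations
    m = 100,                # sampled grid values per iteration
    bandwidth = 50,         # KDE bandwidth, yr
    bin_cutoff = 200,       # site binning dendrogram cut, yr
    collinearity_threshold = 0.70,
    cv_folds = 10,
    num_trees = 500,
    window_width = 200,
    resolution = 1,         # calibration calendar grid step, yr
    kde_grid = seq(0, 7000, by = 20),
    span = c(140, 7000),    # analysis span, yBP
    variants = c("uncorrected", "corrected"),
    isotopes = c("d15N", "d13C"),
    trend_k = 10,
    effect_max_rows = NULL  # PD row subsample cap; NULL = all rows
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
demo_config <- function(seed = 1, ...) {
  pipeline_config(seed = seed, n_individuals = 400,
                  dates_per_zone = c(coastal = 160, "mid-elevation" = 160,
                                     highland = 120),
                  n_draws = 150, n_fits = 40, n_runs = 30, n_iter = 8,
                  m = 25, num_trees = 150, resolution = 5, ...)
}

stage_order <- c("simulate", "qc", "calibrate", "kde", "assign", "trends",
                 "model", "effects", "report")

require_artifact <- function(out_dir, file, stage) {
  path <- file.path(out_dir, file)
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s': run stage '%s' first", file, stage))
  path
}

## Recompute calendar densities for all QC-passing dates (deterministic).
date_densities <- function(dates, curve, resolution) {
  densities <- lapply(seq_len(nrow(dates)), function(i)
    calibrate(dates[i, ], curve, resolution = resolution))
  names(densities) <- dates$lab_id
  densities
}

## Calendar densities for the directly dated individuals.
individual_densities <- function(individuals, curve, resolution) {
  dated <- which(!is.na(individuals$c14_age))
  out <- lapply(dated, function(i)
    calibrate(list(age = individuals$c14_age[i],
                   error = individuals$c14_error[i], marine = FALSE),
              curve, resolution = resolution))
  names(out) <- individuals$id[dated]
  out
}

#' Run one pipeline stage
#'
#' Stages (in order): `simulate` writes the synthetic bundle inputs; `qc`
#' filters individuals and dates; `calibrate` writes median calibrated years
#' per date; `kde` builds per-zone composite KDE ensembles (both variants);
#' `assign` writes the Monte-Carlo exposure table; `trends` writes the
#' per-zone trend ensembles; `model` cross-validates the driver forests and
#' writes diagnostics; `effects` writes the effect decomposition; `report`
#' writes the cumulative climate vs demography table. `all` runs everything.
#'
#' @param name Stage name (or `"all"`).
#' @param config A [pipeline_config].
#' @param out_dir Artifact directory.
#' @return Invisibly, the paths written by the stage.
#' @export
run_stage <- function(name, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") return(run_pipeline(config, out_dir))
  if (!name %in% stage_order) stop("unknown stage: ", name)
  seed <- stage_seed(config$seed, name)
  switch(name,
    simulate = {
      bundle <- simulate_bundle(
        n_individuals = config$n_individuals,
        dates_per_zone = config$dates_per_zone,
        n_fits = config$n_fits, bandwidth = config$bandwidth,
        truth = default_truth(), window_width = config$window_width,
        resolution = max(config$resolution, 5),
        kde_grid = config$kde_grid, seed = config$seed)
      write_bundle(bundle, out_dir)
      invisible(file.path(out_dir, c("individuals.csv", "dates.csv",
                                     "curve.14c", "climate_long.csv",
                                     "truth.json")))
    },
    qc = {
      ind <- read_individuals(require_artifact(out_dir, "individuals.csv",
                                               "simulate"))
      qi <- qc_filter(ind)
      qi$individuals$zone <- classify_zone(qi$individuals$elevation,
                                           qi$individuals$dist_coast)
      write_individuals(qi$individuals,
                        file.path(out_dir, "individuals_qc.csv"))
      write_json_file(qi$report, file.path(out_dir, "qc_report.json"))
      dates <- utils::read.csv(require_artifact(out_dir, "dates.csv",
                                                "simulate"),
                               stringsAsFactors = FALSE)
      qd <- qc_dates(dates)
      qd$dates$zone <- classify_zone(qd$dates$elevation, qd$dates$dist_coast)
      utils::write.csv(qd$dates, file.path(out_dir, "dates_qc.csv"),
                       row.names = FALSE)
      write_json_file(qd$report, file.path(out_dir, "dates_qc_report.json"))
      invisible(file.path(out_dir, c("individuals_qc.csv", "qc_report.json",
                                     "dates_qc.csv",
                                     "dates_qc_report.json")))
    },
    calibrate = {
      dates <- utils::read.csv(require_artifact(out_dir, "dates_qc.csv",
                                                "qc"),
                               stringsAsFactors = FALSE)
      curve <- read_calcurve(require_artifact(out_dir, "curve.14c",
                                              "simulate"))
      dens <- date_densities(dates, curve, config$resolution)
      dates$median_year <- vapply(dens, density_median, numeric(1))
      utils::write.csv(dates[, c("lab_id", "site_id", "zone",
                                 "median_year")],
                       file.path(out_dir, "dates_calibrated.csv"),
                       row.names = FALSE)
      invisible(file.path(out_dir, "dates_calibrated.csv"))
    },
    kde = {
      dates <- utils::read.csv(require_artifact(out_dir, "dates_qc.csv",
                                                "qc"),
                               stringsAsFactors = FALSE)
      med <- utils::read.csv(require_artifact(out_dir,
                                              "dates_calibrated.csv",
                                              "calibrate"),
                             stringsAsFactors = FALSE)
      curve <- read_calcurve(file.path(out_dir, "curve.14c"))
      dates$median_year <- med$median_year[match(dates$lab_id, med$lab_id)]
      dens <- date_densities(dates, curve, config$resolution)
      bins <- bin_dates(dates, cutoff = config$bin_cutoff)
      paths <- character(0)
      for (z in ZONES) {
        idx <- which(dates$zone == z)
        ens <- composite_kde(dens[idx], bins[idx, , drop = FALSE],
                             n_fits = config$n_fits,
                             bandwidth = config$bandwidth,
                             grid = config$kde_grid,
                             seed = stage_seed(seed, z), zone = z)
        pu <- file.path(out_dir, sprintf("kde_%s_uncorrected.csv",
                                         gsub("-", "_", z)))
        write_ensemble(ens, pu)
        pc <- file.path(out_dir, sprintf("kde_%s_corrected.csv",
                                         gsub("-", "_", z)))
        write_ensemble(taphonomic_correct(ens), pc)
        paths <- c(paths, pu, pc)
      }
      invisible(paths)
    },
    assign = {
      ind <- read_individuals(require_artifact(out_dir, "individuals_qc.csv",
                                               "qc"))
      curve <- read_calcurve(file.path(out_dir, "curve.14c"))
      climate <- read_climate(require_artifact(out_dir, "climate_long.csv",
                                               "simulate"))
      ens_u <- read_zone_ensembles(out_dir, "uncorrected")
      ens_c <- read_zone_ensembles(out_dir, "corrected")
      dens <- individual_densities(ind, curve, config$resolution)
      exp <- build_exposures(ind, climate, ens_u, ens_c, densities = dens,
                             n_draws = config$n_draws, seed = seed,
                             span = config$span)
      utils::write.csv(exp, file.path(out_dir, "exposures.csv"),
                       row.names = FALSE)
      invisible(file.path(out_dir, "exposures.csv"))
    },
    trends = {
      ind <- read_individuals(require_artifact(out_dir, "individuals_qc.csv",
                                               "qc"))
      curve <- read_calcurve(file.path(out_dir, "curve.14c"))
      dens <- individual_densities(ind, curve, config$resolution)
      paths <- character(0)
      for (z in ZONES) for (iso in config$isotopes) {
        tr <- fit_trend_ensemble(ind, zone = z, isotope = iso,
                                 n_runs = config$n_runs,
                                 seed = stage_seed(seed, paste0(z, iso)),
                                 k = config$trend_k, densities = dens)
        p <- file.path(out_dir, sprintf("trend_%s_%s.csv",
                                        gsub("-", "_", z), iso))
        utils::write.csv(as.data.frame(tr), p, row.names = FALSE)
        paths <- c(paths, p)
      }
      invisible(paths)
    },
    model = {
      exp <- utils::read.csv(require_artifact(out_dir, "exposures.csv",
                                              "assign"),
                             stringsAsFactors = FALSE)
      ind <- read_individuals(file.path(out_dir, "individuals_qc.csv"))
      paths <- character(0)
      for (iso in config$isotopes) for (variant in config$variants) {
        d <- driver_design(ind, exp, iso, variant)
        diag <- residual_diagnostics(d$design, d$response, d$lat, d$lon,
                                     d$mean_years, k = config$cv_folds,
                                     seed = stage_seed(seed,
                                                       paste0(iso, variant)),
                                     num_trees = config$num_trees)
        p <- file.path(out_dir, sprintf("model_%s_%s.json", iso, variant))
        write_json_file(list(
          isotope = iso, kde_variant = variant, n = length(d$response),
          rmse_cv = diag$rmse_cv,
          pct_variance_explained_cv = diag$pct_variance_explained_cv,
          morans_i = diag$morans_i,
          acf = diag$acf,
          collinearity_flagged = diag$collinearity$flagged), p)
        utils::write.csv(data.frame(individual_id = d$id,
                                    residual = diag$residuals),
                         file.path(out_dir,
                                   sprintf("residuals_%s_%s.csv", iso,
                                           variant)),
                         row.names = FALSE)
        paths <- c(paths, p)
      }
      invisible(paths)
    },
    effects = {
      exp <- utils::read.csv(require_artifact(out_dir, "exposures.csv",
                                              "assign"),
                             stringsAsFactors = FALSE)
      ind <- read_individuals(file.path(out_dir, "individuals_qc.csv"))
      out <- list()
      for (iso in config$isotopes) for (variant in config$variants) {
        d <- driver_design(ind, exp, iso, variant)
        model <- fit_forest(d$design, d$response,
                            num_trees = config$num_trees,
                            seed = stage_seed(seed, paste0(iso, variant)))
        dd <- cbind(d$design, zone = d$zone, stringsAsFactors = FALSE)
        eff <- decompose_effects(model, dd, n_iter = config$n_iter,
                                 m = config$m,
                                 max_rows = config$effect_max_rows,
                                 seed = stage_seed(seed,
                                                   paste0("fx", iso,
                                                          variant)))
        eff$isotope <- iso
        eff$kde_variant <- variant
        out[[paste(iso, variant)]] <- eff
      }
      effects <- do.call(rbind, out)
      rownames(effects) <- NULL
      utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                       row.names = FALSE)
      invisible(file.path(out_dir, "effects.csv"))
    },
    report = {
      effects <- utils::read.csv(require_artifact(out_dir, "effects.csv",
                                                  "effects"),
                                 stringsAsFactors = FALSE)
      cum <- cumulative_comparison(effects)
      utils::write.csv(cum, file.path(out_dir, "cumulative.csv"),
                       row.names = FALSE)
      invisible(file.path(out_dir, "cumulative.csv"))
    })
}

read_zone_ensembles <- function(out_dir, variant) {
  out <- lapply(ZONES, function(z)
    read_ensemble(require_artifact(
      out_dir, sprintf("kde_%s_%s.csv", gsub("-", "_", z), variant),
      "kde")))
  names(out) <- ZONES
  out
}

## Assemble the RF design for one isotope and KDE variant.
driver_design <- function(individuals, exposures, isotope, variant) {
  kde_col <- paste0("kde_", variant)
  idx <- match(exposures$individual_id, individuals$id)
  y <- individuals[[isotope]][idx]
  keep <- !is.na(y) & !is.na(exposures[[kde_col]])
  design <- exposures[keep, CLIMATE_VARS, drop = FALSE]
  design$population <- exposures[[kde_col]][keep]
  list(design = design, response = y[keep],
       zone = exposures$zone[keep],
       id = exposures$individual_id[keep],
       lat = individuals$lat[idx][keep], lon = individuals$lon[idx][keep],
       mean_years = (individuals$date_min[idx][keep] +
                       individuals$date_max[idx][keep]) / 2)
}

#' Run the complete pipeline
#'
#' Executes every stage in order against one output directory. With a fixed
#' config and seed, a rerun produces byte-identical artifacts.
#'
#' @param config A [pipeline_config].
#' @param out_dir Artifact directory.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  for (s in stage_order) run_stage(s, config, out_dir)
  write_json_file(list(config = unclass(config)[setdiff(names(config),
                                                        "kde_grid")],
                       stages = stage_order),
                  file.path(out_dir, "pipeline_metadata.json"))
  invisible(out_dir)
}
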
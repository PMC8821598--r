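## Individual-level isotope data model: inclusion filters and elevation zoning.

#' Classify an individual into an elevation zone
#'
#' Coastal: below 350 masl and within 15 km of the coast. Highland: above
#' 3500 masl. Everything else (including the exact 350 and 3500 m boundaries)
#' is mid-elevation. Thresholds are strict inequalities.
#'
#' @param elevation Elevation in meters above sea level (non-negative).
#' @param dist_coast Distance to the coastline in km (non-negative).
#' @return Character vector of zone labels; see [zones()].
#' @export
classify_zone <- function(elevation, dist_coast) {
  if (any(elevation < 0, na.rm = TRUE) || any(dist_coast < 0, na.rm = TRUE))
    stop("elevation and dist_coast must be non-negative")
  ifelse(elevation < 350 & dist_coast < 15, "coastal",
         ifelse(elevation > 3500, "highland", "mid-elevation"))
}

#' Collagen C:N acceptability
#'
#' A C:N atomic ratio in 2.9-3.6 indicates well-preserved collagen and is
#' accepted outright. Values outside that range are accepted only when the
#' reporting author explicitly accepted the sample (in practice extending the
#' range to about 2.6-3.6). Samples with no per-sample ratio are accepted when
#' the source study validated the whole series in text.
#'
#' @param cn_ratio C:N ratio, or `NA` when unreported.
#' @param author_accepted Logical: reporting author accepted the sample.
#' @param study_validated Logical: study-wide validity confirmed without
#'   per-sample ratios.
#' @return Logical vector.
#' @export
cn_acceptable <- function(cn_ratio, author_accepted = FALSE,
                          study_validated = FALSE) {
  if (any(!is.na(cn_ratio) & cn_ratio <= 0))
    stop("cn_ratio must be positive when present")
  n <- max(length(cn_ratio), length(author_accepted), length(study_validated))
  cn <- rep_len(cn_ratio, n)
  aa <- rep_len(as.logical(author_accepted), n)
  sv <- rep_len(as.logical(study_validated), n)
  in_range <- !is.na(cn) & cn >= 2.9 & cn <= 3.6
  in_range | (aa %in% TRUE) | (is.na(cn) & sv %in% TRUE)
}

## Minimum age in years implied by an age_class entry. Numeric strings pass
## through; common osteological categories map to their youngest plausible
## age; unknowns give NA (and are retained by qc_filter: exclusion requires
## evidence of being under five).
#' @rdname qc_filter
#' @param age_class Numeric age or age-category label.
#' @export
age_min <- function(age_class) {
  lut <- c(infant = 0, child = 3, juvenile = 5, subadult = 12,
           adolescent = 12, adult = 18, "young adult" = 18,
           "middle adult" = 35, "old adult" = 50)
  vapply(as.character(age_class), function(a) {
    if (is.na(a) || !nzchar(a)) return(NA_real_)
    num <- suppressWarnings(as.numeric(a))
    if (!is.na(num)) return(num)
    key <- tolower(trimws(a))
    if (key %in% names(lut)) lut[[key]] else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Apply the inclusion filters to an individual-level isotope table
#'
#' Filters are applied in a fixed, recorded order: (1) individuals known to be
#' under five years old are dropped to control for weaning enrichment;
#' (2) individuals failing the collagen C:N rule ([cn_acceptable]) are
#' dropped; (3) Colonial Period individuals are dropped to restrict the
#' sample to pre-contact diets. Individuals of unknown age are retained.
#'
#' @param individuals Data frame with at least `age_class`, `cn_ratio`,
#'   `author_accepted`, `study_validated`, `period`, `d13C`, `d15N`.
#' @return A list with `individuals` (the retained rows) and `report`, a
#'   named list of counts per rule (input, dropped_age, dropped_cn,
#'   dropped_colonial, retained, retained_d15N, retained_d13C,
#'   no_cn_included).
#' @export
qc_filter <- function(individuals) {
  x <- individuals
  n_input <- nrow(x)

  amin <- if (nrow(x)) age_min(x$age_class) else numeric(0)
  keep_age <- is.na(amin) | amin >= 5
  n_age <- sum(!keep_age)
  x <- x[keep_age, , drop = FALSE]

  keep_cn <- if (nrow(x))
    cn_acceptable(x$cn_ratio, x$author_accepted, x$study_validated)
  else logical(0)
  n_cn <- sum(!keep_cn)
  x <- x[keep_cn, , drop = FALSE]

  colonial <- if (nrow(x))
    tolower(trimws(as.character(x$period))) == "colonial" else logical(0)
  colonial[is.na(colonial)] <- FALSE
  n_col <- sum(colonial)
  x <- x[!colonial, , drop = FALSE]

  report <- list(
    input = n_input,
    dropped_age = n_age,
    dropped_cn = n_cn,
    dropped_colonial = n_col,
    retained = nrow(x),
    retained_d15N = sum(!is.na(x$d15N)),
    retained_d13C = sum(!is.na(x$d13C)),
    no_cn_included = sum(is.na(x$cn_ratio)),
    filter_order = c("age", "cn", "colonial")
  )
  list(individuals = x, report = report)
}

#' Read / write an individual-level isotope table
#'
#' @param path CSV path (header row, UTF-8, '.' decimal).
#' @return `read_individuals` returns a data frame.
#' @export
read_individuals <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_individuals
#' @param individuals Data frame of individuals.
#' @export
write_individuals <- function(individuals, path) {
  utils::write.csv(individuals, path, row.names = FALSE)
  invisible(path)
}

#' Great-circle distance to a coastline polyline
#'
#' Optional helper for datasets that lack a precomputed distance-to-coast
#' column: the minimum haversine distance from each point to the vertices of
#' a user-supplied coastline polyline.
#'
#' @param lat,lon Point coordinates in decimal degrees.
#' @param coast Data frame with `lat` and `lon` columns describing the
#'   coastline polyline (vertices densely spaced relative to 15 km).
#' @return Distances in km.
#' @export
dist_to_coast <- function(lat, lon, coast) {
  pts <- cbind(lon, lat)
  cl <- cbind(coast$lon, coast$lat)
  apply(geosphere::distm(pts, cl, fun = geosphere::distHaversine), 1L, min) /
    1000
}
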
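#' @keywords internal
"_PACKAGE"

## The three elevation strata used throughout: coastal (agro-marine),
## mid-elevation (agrarian), highland (agro-pastoral).
ZONES <- c("coastal", "mid-elevation", "highland")

## Covariates entering the driver models, in fixed order.
CLIMATE_VARS <- c("temp", "temp_seasonality", "precip", "precip_seasonality")

#' Elevation zone and climate variable labels
#'
#' @return Character vector of the three elevation zone labels, or of the four
#'   climate covariate names, in canonical order.
#' @export
zones <- function() ZONES

#' @rdname zones
#' @export
climate_vars <- function() CLIMATE_VARS

## Trapezoidal integral on an ascending grid.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

## Derive a reproducible sub-seed for a named pipeline stage from one master
## seed. Kept below 2^31 - 1 so it is always a valid R integer seed.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 7919) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

## Nearest index on a uniform ascending grid, ties resolved toward the
## smaller grid value (= younger year BP on an ascending yBP grid).
nearest_index_ascending <- function(x, grid) {
  by <- grid[2L] - grid[1L]
  idx <- ceiling((x - grid[1L]) / by - 0.5) + 1L
  pmin(pmax(idx, 1L), length(grid))
}

## Nearest index on a uniform descending yBP grid, ties toward the younger
## (smaller yBP) value, which sits at the larger index.
nearest_index_descending <- function(x, grid) {
  by <- grid[1L] - grid[2L]
  idx <- floor((grid[1L] - x) / by + 0.5) + 1L
  pmin(pmax(idx, 1L), length(grid))
}

## Great-circle distance matrix in km between points given as lon/lat degrees.
distance_matrix_km <- function(lat, lon) {
  pts <- cbind(lon, lat)
  geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
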
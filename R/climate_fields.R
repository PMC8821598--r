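## Gridded climate time series container: four variables (mean temperature,
## temperature seasonality, mean precipitation, precipitation seasonality) on
## a regular lat/lon grid at a uniform 20-year step, emulating coarse GCM
## simulation output.

#' Construct a climate field set
#'
#' @param lats,lons Cell-center latitudes and longitudes (regular grid,
#'   ascending).
#' @param steps Time steps in calendar years BP, uniform spacing, descending
#'   (oldest first).
#' @param values Named list of four matrices (cell x step), names
#'   [climate_vars()]. Cells are ordered as `expand.grid(lon = lons,
#'   lat = lats)` row-major over latitude.
#' @return Object of class `climate_fields`.
#' @export
climate_fields <- function(lats, lons, steps, values) {
  if (length(lats) == 0L || length(lons) == 0L) stop("empty grid")
  if (!all(CLIMATE_VARS %in% names(values)))
    stop("values must contain the four climate variables")
  ncell <- length(lats) * length(lons)
  for (v in CLIMATE_VARS) {
    if (!all(dim(values[[v]]) == c(ncell, length(steps))))
      stop("each variable must be a complete cell x step matrix")
    if (any(!is.finite(values[[v]]))) stop("missing cell x step values")
  }
  if (length(steps) > 1L && stats::sd(diff(steps)) > 1e-9)
    stop("steps must be uniformly spaced")
  cells <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  cells <- data.frame(id = seq_len(nrow(cells)), lat = cells$lat,
                      lon = cells$lon)
  structure(list(lats = as.numeric(lats), lons = as.numeric(lons),
                 cells = cells, steps = as.numeric(steps),
                 values = values[CLIMATE_VARS]),
            class = "climate_fields")
}

#' @export
print.climate_fields <- function(x, ...) {
  cat(sprintf("<climate_fields> %d cells (%.1f-%.1f lat, %.1f-%.1f lon), %d steps %g-%g yBP\n",
              nrow(x$cells), min(x$lats), max(x$lats), min(x$lons),
              max(x$lons), length(x$steps), x$steps[1L],
              x$steps[length(x$steps)]))
  invisible(x)
}

## Nearest cell-center id for coordinates; errors outside the grid hull
## (half a cell spacing beyond the extreme centers).
nearest_cell <- function(fields, lat, lon) {
  dlat <- if (length(fields$lats) > 1L) diff(fields$lats[1:2]) else 2.5
  dlon <- if (length(fields$lons) > 1L) diff(fields$lons[1:2]) else 2.5
  if (any(lat < min(fields$lats) - dlat / 2 | lat > max(fields$lats) + dlat / 2 |
          lon < min(fields$lons) - dlon / 2 | lon > max(fields$lons) + dlon / 2))
    stop(sprintf("coordinates outside climate grid (lat %g..%g, lon %g..%g)",
                 min(fields$lats), max(fields$lats), min(fields$lons),
                 max(fields$lons)))
  li <- nearest_index_ascending(lat, fields$lats)
  lo <- nearest_index_ascending(lon, fields$lons)
  (li - 1L) * length(fields$lons) + lo
}

#' Read / write a climate field set as a long CSV
#'
#' Long format: `cell_id, lat, lon, year_bp, variable, value`.
#'
#' @param fields A [climate_fields] object.
#' @param path CSV path.
#' @export
write_climate <- function(fields, path) {
  rows <- do.call(rbind, lapply(CLIMATE_VARS, function(v) {
    data.frame(cell_id = rep(fields$cells$id, times = length(fields$steps)),
               lat = rep(fields$cells$lat, times = length(fields$steps)),
               lon = rep(fields$cells$lon, times = length(fields$steps)),
               year_bp = rep(fields$steps, each = nrow(fields$cells)),
               variable = v,
               value = as.numeric(fields$values[[v]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate
#' @export
read_climate <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  lats <- sort(unique(x$lat))
  lons <- sort(unique(x$lon))
  steps <- unique(x$year_bp[x$variable == CLIMATE_VARS[1L] &
                              x$cell_id == x$cell_id[1L]])
  ncell <- length(lats) * length(lons)
  values <- lapply(CLIMATE_VARS, function(v) {
    sub <- x[x$variable == v, ]
    sub <- sub[order(match(sub$year_bp, steps), sub$cell_id), ]
    matrix(sub$value, nrow = ncell, ncol = length(steps))
  })
  names(values) <- CLIMATE_VARS
  climate_fields(lats, lons, steps, values)
}
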
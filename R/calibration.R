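## Radiocarbon calibration against a supplied curve, with marine reservoir
## offsets, plus sampling and summaries of the resulting calendar densities.

#' Construct a calibration curve object
#'
#' A calibration curve maps calendar years BP to conventional radiocarbon ages
#' with a 1-sigma uncertainty, in the standard 3-column layout used by the
#' published curve files (calBP, 14C age, 1 sigma).
#'
#' @param cal_bp Strictly increasing calendar years BP grid.
#' @param mu Curve radiocarbon age (14C yr BP) at each grid point.
#' @param sigma Curve 1-sigma uncertainty (14C yr); all positive.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(cal_bp, mu, sigma) {
  if (length(cal_bp) != length(mu) || length(mu) != length(sigma))
    stop("cal_bp, mu and sigma must have equal length")
  if (any(diff(cal_bp) <= 0)) stop("cal_bp must be strictly increasing")
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(list(cal_bp = as.numeric(cal_bp), mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d knots, %g-%g cal BP\n",
              length(x$cal_bp), min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

#' Read / write a 3-column calibration curve file
#'
#' Files follow the published curve dialect: three numeric columns
#' (calBP, 14C age, 1 sigma), comma- or whitespace-separated, with `#`
#' comment lines. Rows may be in either calBP order.
#'
#' @param path File path.
#' @return `read_calcurve` returns a `calibration_curve`.
#' @export
read_calcurve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lines <- gsub(",", " ", lines)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(f)
    as.numeric(f[1:3])))
  m <- m[order(m[, 1L]), , drop = FALSE]
  calibration_curve(m[, 1L], m[, 2L], m[, 3L])
}

#' @rdname read_calcurve
#' @param curve A `calibration_curve`.
#' @export
write_calcurve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# calBP, 14C age BP, 1 sigma", con)
  writeLines(sprintf("%.1f,%.6f,%.6f", curve$cal_bp, curve$mu, curve$sigma),
             con)
  invisible(path)
}

#' Construct a calendar-year probability density
#'
#' @param years Calendar year BP grid (ascending).
#' @param p Probability mass at each year; non-negative, summing to one.
#' @return An object of class `calendar_density`.
#' @export
calendar_density <- function(years, p) {
  if (length(years) != length(p)) stop("years and p must have equal length")
  if (any(p < 0)) stop("probability mass must be non-negative")
  s <- sum(p)
  if (abs(s - 1) > 1e-9) stop("probability mass must sum to 1")
  structure(list(years = as.numeric(years), p = as.numeric(p)),
            class = "calendar_density")
}

#' @export
print.calendar_density <- function(x, ...) {
  cat(sprintf("<calendar_density> %d years, median %g cal BP\n",
              length(x$years), density_median(x)))
  invisible(x)
}

#' Calibrate a radiocarbon measurement
#'
#' For each calendar grid year t the unnormalized weight is the Gaussian
#' density of the (reservoir-adjusted) measured age at mean mu(t) with
#' standard deviation sqrt(error^2 + sigma(t)^2 + delta_r_error^2). Marine
#' measurements have their local reservoir offset delta_r subtracted from the
#' measured age and its uncertainty added in quadrature; for non-marine
#' measurements the delta_r fields are ignored. The curve is interpolated
#' linearly onto a uniform calendar grid, the weights normalized to sum to
#' one, and mass below `floor` times the maximum trimmed and renormalized.
#'
#' @param m A list or one-row data frame with fields `age`, `error`, and
#'   optionally `marine`, `delta_r`, `delta_r_error`.
#' @param curve A [calibration_curve].
#' @param resolution Calendar grid step in years (default 1).
#' @param floor Trimming floor as a fraction of the maximum mass.
#' @return A [calendar_density].
#' @export
calibrate <- function(m, curve, resolution = 1, floor = 1e-5) {
  age <- as.numeric(m$age)
  err <- as.numeric(m$error)
  marine <- isTRUE(as.logical(m$marine))
  dr <- if (marine && !is.null(m$delta_r) && !is.na(m$delta_r))
    as.numeric(m$delta_r) else 0
  dr_err <- if (marine && !is.null(m$delta_r_error) && !is.na(m$delta_r_error))
    as.numeric(m$delta_r_error) else 0
  adj <- age - dr

  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  mu_g <- stats::approx(curve$cal_bp, curve$mu, xout = grid)$y
  sd_g <- sqrt(err^2 + stats::approx(curve$cal_bp, curve$sigma,
                                     xout = grid)$y^2 + dr_err^2)
  if (adj < min(mu_g) - 6 * max(sd_g) || adj > max(mu_g) + 6 * max(sd_g))
    stop(sprintf(
      "age %g (reservoir-adjusted) outside curve span [%g, %g] 14C BP",
      adj, min(mu_g), max(mu_g)))
  w <- stats::dnorm(adj, mean = mu_g, sd = sd_g)
  if (sum(w) <= 0)
    stop(sprintf("age %g carries no mass on curve span [%g, %g] cal BP",
                 adj, min(grid), max(grid)))
  p <- w / sum(w)
  keep <- p >= floor * max(p)
  calendar_density(grid[keep], p[keep] / sum(p[keep]))
}

#' Sample calendar years from a calibrated density
#'
#' I.i.d. draws with replacement proportional to the probability mass.
#'
#' @param d A [calendar_density].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of calendar years BP.
#' @export
sample_years <- function(d, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    if (length(d$years) == 1L) rep(d$years, n)
    else d$years[sample.int(length(d$years), n, replace = TRUE, prob = d$p)]
  })
}

#' Median of a calendar density
#'
#' The smallest grid year at which the cumulative mass reaches 0.5.
#'
#' @param d A [calendar_density].
#' @return Calendar year BP.
#' @export
density_median <- function(d) {
  d$years[which(cumsum(d$p) >= 0.5)[1L]]
}
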
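## Random-forest driver models of isotope values on climate + population
## covariates: collinearity screen, seeded fitting, tenfold cross-validation
## and spatial/temporal residual diagnostics.

#' Pairwise collinearity screen
#'
#' Reports pairwise Pearson correlations between candidate predictors and
#' flags pairs at or above the threshold. Flagged variables are reported but
#' retained: the ensemble model tolerates correlated predictors, and the
#' screen exists to make the collinearity structure visible.
#'
#' @param design Data frame of numeric predictors (at least two columns).
#' @param threshold Absolute correlation flag threshold (default 0.70,
#'   honored exactly at the boundary).
#' @return List with `kept` (all variable names), `r` (correlation matrix)
#'   and `flagged` (data frame of flagged pairs, possibly empty).
#' @export
collinearity_screen <- function(design, threshold = 0.70) {
  if (ncol(design) < 2L) stop("need at least two variables")
  if (any(vapply(design, function(x) stats::sd(x) == 0, logical(1))))
    stop("constant column: correlation undefined")
  r <- stats::cor(design)
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(r)[pairs[, 1L]],
                        var2 = colnames(r)[pairs[, 2L]],
                        r = r[pairs], stringsAsFactors = FALSE)
  list(kept = colnames(design), r = r, flagged = flagged)
}

#' Fit a random-forest driver model
#'
#' Seeded, single-threaded ensemble regression of an isotope response on the
#' five covariate means (four climate variables plus one population-proxy
#' variant). Hyperparameter defaults follow the common regression-forest
#' convention: 500 trees, floor(p/3) candidate variables per split, minimum
#' node size 5.
#'
#' @param design Data frame of predictors (no missing values).
#' @param response Numeric response (per mil).
#' @param num_trees,mtry,min_node_size Forest hyperparameters.
#' @param seed Integer seed.
#' @return Object of class `forest_model` wrapping the fitted ensemble with
#'   its hyperparameters and training metadata.
#' @export
fit_forest <- function(design, response, num_trees = 500,
                       mtry = max(1L, floor(ncol(design) / 3)),
                       min_node_size = 5, seed = 1) {
  if (nrow(design) < 20) stop("need at least 20 observations")
  if (anyNA(design) || anyNA(response)) stop("missing values in design/response")
  df <- cbind(design, .response = response)
  fit <- ranger::ranger(dependent.variable.name = ".response", data = df,
                        num.trees = num_trees, mtry = mtry,
                        min.node.size = min_node_size, seed = seed,
                        num.threads = 1L)
  structure(list(fit = fit, predictors = colnames(design),
                 hyper = list(num_trees = num_trees, mtry = mtry,
                              min_node_size = min_node_size, seed = seed),
                 n = nrow(design), r2_oob = fit$r.squared),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> n=%d trees=%d mtry=%d OOB R2=%.3f\n",
              x$n, x$hyper$num_trees, x$hyper$mtry, x$r2_oob))
  invisible(x)
}

#' @export
predict.forest_model <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit,
                            data = newdata[, object$predictors,
                                           drop = FALSE],
                            num.threads = 1L)$predictions)
}

#' K-fold cross-validation of the driver model
#'
#' Random fold assignment; out-of-fold predictions give the root mean square
#' error and VEcv, the percent of variance explained by cross-validation:
#' 100 * (1 - sum((y - yhat)^2) / sum((y - ybar)^2)).
#'
#' @param design,response As in [fit_forest].
#' @param k Number of folds (default 10).
#' @param seed Integer seed (fold split and forests).
#' @param ... Passed to [fit_forest].
#' @return List: `rmse`, `pct_variance_explained`, `predictions`
#'   (out-of-fold), `folds`.
#' @export
cross_validate <- function(design, response, k = 10, seed = 1, ...) {
  n <- nrow(design)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k observations")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    m <- fit_forest(design[!hold, , drop = FALSE], response[!hold],
                    seed = seed, ...)
    pred[hold] <- predict(m, design[hold, , drop = FALSE])
  }
  rmse <- sqrt(mean((response - pred)^2))
  pct <- 100 * (1 - sum((response - pred)^2) /
                  sum((response - mean(response))^2))
  list(rmse = rmse, pct_variance_explained = pct, predictions = pred,
       folds = folds)
}

#' Moran's I on an inverse-distance weight matrix
#'
#' Spatial autocorrelation of a variable over point coordinates, with
#' weights w_ij = 1 / d_ij (great-circle distance in km, floored at
#' `floor_km` to bound the weight of near-coincident points) and zero
#' diagonal. The expected value under no autocorrelation is -1/(n-1).
#'
#' @param x Numeric variable (e.g. model residuals).
#' @param lat,lon Coordinates in decimal degrees.
#' @param floor_km Distance floor in km (default 1).
#' @return List with `observed`, `expected`, `sd`, `p.value`.
#' @export
morans_i <- function(x, lat, lon, floor_km = 1) {
  if (length(x) < 3) stop("need at least 3 observations")
  d <- distance_matrix_km(lat, lon)
  w <- 1 / pmax(d, floor_km)
  diag(w) <- 0
  moran_stat(x, w)
}

## Moran's I with the weight matrix taken as supplied (no row
## standardization), with the usual randomization-based variance and a
## two-sided normal-approximation p-value.
moran_stat <- function(x, w) {
  n <- length(x)
  y <- x - mean(x)
  s0 <- sum(w)
  obs <- (n / s0) * sum(w * outer(y, y)) / sum(y^2)
  ei <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  k <- (sum(y^4) / n) / (sum(y^2) / n)^2
  v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
          k * (n * (n - 1) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  sdi <- sqrt(v)
  list(observed = obs, expected = ei, sd = sdi,
       p.value = 2 * stats::pnorm(-abs((obs - ei) / sdi)))
}

#' Residual diagnostics for a driver model
#'
#' Residuals are out-of-fold cross-validation residuals. Temporal structure:
#' residual means binned to 20-year steps of each individual's mean death
#' year, in chronological order, summarized by the autocorrelation function.
#' Spatial structure: observed vs expected Moran's I on the inverse-distance
#' matrix.
#'
#' @param design,response As in [fit_forest].
#' @param lat,lon Individual coordinates.
#' @param mean_years Mean death year (yBP) per individual.
#' @param k,seed,... Passed to [cross_validate].
#' @return List (`diagnostics_report`): `rmse_cv`,
#'   `pct_variance_explained_cv`, `residuals`, `acf` (lag in years + value),
#'   `morans_i`, `collinearity`.
#' @export
residual_diagnostics <- function(design, response, lat, lon, mean_years,
                                 k = 10, seed = 1, ...) {
  if (nrow(design) < 3) stop("need at least 3 observations")
  cv <- cross_validate(design, response, k = k, seed = seed, ...)
  res <- response - cv$predictions
  step <- round(mean_years / 20) * 20
  agg <- tapply(res, step, mean)
  ord <- order(as.numeric(names(agg)))
  series <- as.numeric(agg[ord])
  a <- stats::acf(series, plot = FALSE, demean = TRUE)
  mi <- morans_i(res, lat, lon)
  structure(list(rmse_cv = cv$rmse,
                 pct_variance_explained_cv = cv$pct_variance_explained,
                 residuals = res,
                 acf = data.frame(lag_yr = as.numeric(a$lag) * 20,
                                  acf = as.numeric(a$acf)),
                 morans_i = mi,
                 collinearity = collinearity_screen(design)),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics_report> CV RMSE=%.3f, VEcv=%.2f%%, Moran's I=%.4f (p=%.3g)\n",
              x$rmse_cv, x$pct_variance_explained_cv, x$morans_i$observed,
              x$morans_i$p.value))
  invisible(x)
}
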
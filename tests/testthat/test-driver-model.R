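test_that("the collinearity screen flags duplicated but not independent columns", {
  set.seed(1)
  x <- rnorm(1000)
  dup <- data.frame(a = x, b = x, c = rnorm(1000))
  scr <- collinearity_screen(dup)
  expect_true(any(scr$flagged$var1 == "a" & scr$flagged$var2 == "b"))
  expect_equal(scr$flagged$r[1], 1)

  indep <- as.data.frame(matrix(rnorm(5000), ncol = 5))
  expect_equal(nrow(collinearity_screen(indep)$flagged), 0)

  # threshold honored at the boundary
  u <- scale(rnorm(500))[, 1]
  v <- scale(residuals(lm(rnorm(500) ~ u)))[, 1]
  strong <- data.frame(a = u, b = 0.71 * u + sqrt(1 - 0.71^2) * v)
  weak <- data.frame(a = u, b = 0.69 * u + sqrt(1 - 0.69^2) * v)
  expect_equal(nrow(collinearity_screen(strong)$flagged), 1)
  expect_equal(nrow(collinearity_screen(weak)$flagged), 0)

  expect_error(collinearity_screen(data.frame(a = rep(1, 10),
                                              b = rnorm(10))),
               "constant")
})

test_that("the forest learns noiseless signal and nothing from pure noise", {
  set.seed(2)
  n <- 2000
  design <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- sin(6 * design$x1)
  m <- fit_forest(design, y, seed = 3, num_trees = 200)
  r2 <- 1 - sum((predict(m, design) - y)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.95)

  noise <- rnorm(1000)
  cvn <- cross_validate(data.frame(x1 = runif(1000), x2 = runif(1000)),
                        noise, k = 5, seed = 4, num_trees = 100)
  # no explanatory power: VEcv at or below zero up to noise (it is
  # typically slightly negative out of fold)
  expect_lt(cvn$pct_variance_explained, 5)

  expect_identical(predict(fit_forest(design, y, seed = 5), design),
                   predict(fit_forest(design, y, seed = 5), design))
  expect_error(fit_forest(design[1:10, ], y[1:10]), "at least 20")
})

test_that("cross-validation behaves at the extremes and is reproducible", {
  set.seed(6)
  n <- 600
  design <- data.frame(x = runif(n), z = runif(n))
  y <- design$x
  cv <- cross_validate(design, y, k = 10, seed = 7, num_trees = 200)
  expect_gt(cv$pct_variance_explained, 95)
  expect_lt(cv$rmse, 0.1 * sd(y))

  perm <- cross_validate(design, sample(y), k = 10, seed = 8,
                         num_trees = 100)
  expect_lte(perm$pct_variance_explained, 5)

  cv2 <- cross_validate(design, y, k = 10, seed = 7, num_trees = 200)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(design, y, k = 1), "at least 2")
})

test_that("Moran's I matches a brute-force evaluation and its closed-form mean", {
  # 4-point toy with hand-set residuals
  lat <- c(-10, -10.5, -14, -14.4)
  lon <- c(-75, -75.3, -71, -71.2)
  r <- c(1.2, -0.4, 0.7, -1.5)
  got <- morans_i(r, lat, lon)
  expect_equal(got$expected, -1 / 3, tolerance = 1e-12)

  d <- geosphere::distm(cbind(lon, lat),
                        fun = geosphere::distHaversine) / 1000
  w <- 1 / pmax(d, 1); diag(w) <- 0
  rc <- r - mean(r)
  n <- 4
  oracle <- (n / sum(w)) * sum(w * outer(rc, rc)) / sum(rc^2)
  expect_equal(got$observed, oracle, tolerance = 1e-12)
})

test_that("Moran machinery agrees with ape on row-standardized weights", {
  set.seed(20)
  n <- 25
  lat <- runif(n, -18, -6)
  lon <- runif(n, -79, -69)
  x <- rnorm(n)
  d <- geosphere::distm(cbind(lon, lat),
                        fun = geosphere::distHaversine) / 1000
  w <- 1 / pmax(d, 1); diag(w) <- 0
  w_std <- w / rowSums(w)
  mine <- paleodiet:::moran_stat(x, w_std)
  ref <- ape::Moran.I(x, w)   # ape row-standardizes internally
  expect_equal(mine$observed, ref$observed, tolerance = 1e-12)
  expect_equal(mine$sd, ref$sd, tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("clustered residuals are detected as spatial autocorrelation", {
  set.seed(9)
  n <- 40
  lat <- c(rnorm(n / 2, -8, 0.05), rnorm(n / 2, -15, 0.05))
  lon <- c(rnorm(n / 2, -75, 0.05), rnorm(n / 2, -70, 0.05))
  r <- c(rnorm(n / 2, 1, 0.1), rnorm(n / 2, -1, 0.1))
  got <- morans_i(r, lat, lon)
  expect_gt(got$observed, got$expected)
  expect_lt(got$p.value, 0.01)
})

test_that("residual diagnostics report acf, Moran's I and CV metrics together", {
  d <- shared_design()
  diag <- residual_diagnostics(d$design, d$response, d$lat, d$lon, d$years,
                               k = 5, seed = 10, num_trees = 100)
  expect_equal(diag$acf$acf[1], 1)          # lag 0
  expect_true(all(abs(diag$acf$acf) <= 1))
  expect_equal(diag$morans_i$expected,
               -1 / (length(d$response) - 1))
  expect_true(diag$rmse_cv > 0)
  # synthetic truth has noise: explained variance is high but below 100
  expect_true(diag$pct_variance_explained_cv > 40 &&
                diag$pct_variance_explained_cv < 100)
  expect_s3_class(diag$collinearity$flagged, "data.frame")
})

test_that("CV variance explained tracks the generator's signal share", {
  climate <- simulate_climate_fields(seed = 12)
  grid <- seq(0, 7000, by = 20)
  dens <- dnorm(grid, 2500, 900)
  single <- population_ensemble("coastal", grid,
                                matrix(dens / paleodiet:::trapz(grid, dens),
                                       1), bandwidth = 50)
  ens <- list("coastal" = single, "mid-elevation" = single,
              "highland" = single)
  truth <- default_truth()   # 85% signal share, 15% noise
  ind <- simulate_individuals(2000, climate, ens, truth, window_width = 0,
                              seed = 13, dated_fraction = 0,
                              missing_d15N = 0)
  # exact covariates (degenerate windows) isolate the model's behaviour
  design <- data.frame(temp = ind$true_temp,
                       temp_seasonality = ind$true_temp_seasonality,
                       precip = ind$true_precip,
                       precip_seasonality = ind$true_precip_seasonality,
                       population = ind$true_population)
  # remove the between-zone intercept differences the design cannot see
  y <- ind$d15N - truth$baseline_d15N[ind$zone]
  cv <- cross_validate(design, y, k = 10, seed = 14, num_trees = 200)
  expect_lt(abs(cv$pct_variance_explained - 85), 10)
})
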
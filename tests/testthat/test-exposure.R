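test_that("window sampling covers degenerate, uniform and calibrated cases", {
  expect_true(all(window_sampler(list(date_min = 3000, date_max = 3000),
                                 100, seed = 1) == 3000))

  u <- window_sampler(list(date_min = 1000, date_max = 1200), 10000,
                      seed = 2)
  expect_lt(abs(mean(u) - 1100), 2)
  expect_true(all(u >= 1000 & u <= 1200))

  # bimodal calibrated density: draw histogram matches the density
  bi <- calendar_density(c(2000, 2010, 2500, 2510),
                         c(0.35, 0.35, 0.15, 0.15))
  d <- window_sampler(list(date_min = 1900, date_max = 2600, density = bi),
                      10000, seed = 3)
  obs <- table(factor(d, levels = bi$years))
  expect_gt(chisq.test(obs, p = bi$p)$p.value, 0.01)

  expect_error(window_sampler(list(date_min = 100, date_max = 200,
                                   density = bi), 10),
               "no mass inside window")
})

test_that("climate assignment averages the right cells and steps", {
  const <- simulate_climate_fields(innovation_sd = c(temp = 0,
                                                     temp_seasonality = 0,
                                                     precip = 0,
                                                     precip_seasonality = 0),
                                   seed = 1)
  cell <- paleodiet:::nearest_cell(const, -10.1, -74.9)
  m <- assign_climate(const, -10.1, -74.9,
                      sample(seq(200, 6000), 500, replace = TRUE))
  expect_equal(m[["temp"]], const$values$temp[cell, 1])

  # field linear in time: window mean ~ field at window midpoint
  lin <- const
  slope <- 0.001
  lin$values$temp <- matrix(rep(slope * lin$steps, each = nrow(lin$cells)),
                            nrow(lin$cells))
  yrs <- window_sampler(list(date_min = 2000, date_max = 3000), 20000,
                        seed = 4)
  m2 <- assign_climate(lin, -10.1, -74.9, yrs)
  expect_lt(abs(m2[["temp"]] - slope * 2500), slope * 20)

  # degenerate window gives the exact step value
  m3 <- assign_climate(lin, -10.1, -74.9, rep(2500, 10))
  step <- paleodiet:::nearest_index_descending(2500, lin$steps)
  expect_equal(m3[["temp"]], lin$values$temp[cell, step])

  expect_error(assign_climate(const, 40, -74.9, 3000), "outside")
})

test_that("population assignment averages fits and years correctly", {
  flat <- flat_ensemble(n_fits = 5)
  v <- assign_population(flat, window_sampler(list(date_min = 1000,
                                                   date_max = 2000), 500,
                                              seed = 5), seed = 6)
  expect_equal(v, 1 / 7000, tolerance = 1e-12)

  # single fit, degenerate window: exact density value
  grid <- seq(0, 7000, by = 20)
  dens <- dnorm(grid, 3000, 800)
  fits <- matrix(dens / paleodiet:::trapz(grid, dens), 1)
  single <- population_ensemble("coastal", grid, fits, bandwidth = 50)
  expect_equal(assign_population(single, rep(3000, 100), seed = 7),
               fits[1, which(grid == 3000)])

  # two fits, two-year window: mean ~ average of the four values
  f2 <- fits * 0.5
  f2 <- rbind(fits, 2 * fits / paleodiet:::trapz(grid, 2 * fits[1, ]))
  two <- population_ensemble("coastal", grid, f2, bandwidth = 50)
  yrs <- window_sampler(list(date_min = 3000, date_max = 3001), 40000,
                        seed = 8)
  got <- assign_population(two, yrs, seed = 9)
  i1 <- which(grid == 3000)
  exp_val <- mean(c(f2[, i1], f2[, i1]))  # 3001 maps to the 3000 step
  expect_lt(abs(got - exp_val) / exp_val, 0.02)

  expect_error(assign_population(single, 9000), "outside ensemble grid")
})

test_that("z-scores standardize every cell series and average across cells", {
  f <- simulate_climate_fields(seed = 10)
  zs <- climate_zscores(f)
  for (v in climate_vars()) {
    expect_lt(max(abs(rowMeans(zs$z[[v]]))), 1e-9)
    expect_lt(max(abs(apply(zs$z[[v]], 1, sd) - 1)), 1e-9)
  }
  const <- simulate_climate_fields(innovation_sd = c(temp = 0,
                                                     temp_seasonality = 0,
                                                     precip = 0,
                                                     precip_seasonality = 0),
                                   seed = 11)
  w <- capture_warnings(zc <- climate_zscores(const))
  expect_true(any(grepl("zero-variance", w)))
  expect_true(all(zc$z$temp == 0))

  # two-cell toy: central line equals the hand-computed average
  toy <- climate_fields(lats = c(-10, -7.5), lons = -75,
                        steps = seq(200, 100, by = -20),
                        values = lapply(setNames(climate_vars(),
                                                 climate_vars()),
                                        function(v) rbind(1:6, seq(2, 12, 2))))
  zt <- climate_zscores(toy, smooth_window = 1)
  hand <- colMeans((rbind(1:6, seq(2, 12, 2)) -
                      c(mean(1:6), mean(seq(2, 12, 2)))) /
                     c(sd(1:6), sd(seq(2, 12, 2))))
  expect_equal(zt$central$mean_z[zt$central$variable == "temp"], hand)
})

test_that("exposure records are seed-reproducible and converge with draws", {
  b <- shared_bundle()
  ind <- b$individuals[1:25, ]
  e1 <- suppressWarnings(build_exposures(ind, b$climate, b$ensembles,
                                         n_draws = 200, seed = 3))
  e2 <- suppressWarnings(build_exposures(ind, b$climate, b$ensembles,
                                         n_draws = 200, seed = 3))
  expect_identical(e1, e2)

  e4 <- suppressWarnings(build_exposures(ind, b$climate, b$ensembles,
                                         n_draws = 6400, seed = 3))
  e8 <- suppressWarnings(build_exposures(ind, b$climate, b$ensembles,
                                         n_draws = 12800, seed = 3))
  for (v in climate_vars()) {
    rng <- diff(range(b$climate$values[[v]]))
    expect_lt(max(abs(e4[[v]] - e8[[v]])), 0.005 * rng)
  }
})

test_that("noiseless degenerate-window exposures equal the true covariates", {
  climate <- simulate_climate_fields(seed = 12)
  grid <- seq(0, 7000, by = 20)
  dens <- dnorm(grid, 2500, 900)
  fits <- matrix(dens / paleodiet:::trapz(grid, dens), 1)
  single <- population_ensemble("coastal", grid, fits, bandwidth = 50)
  ens <- list("coastal" = single, "mid-elevation" = single,
              "highland" = single)
  ind <- simulate_individuals(40, climate, ens,
                              default_truth(noise_sd = 0,
                                            effect_shares = c(precip = 1)),
                              window_width = 0, seed = 13,
                              dated_fraction = 0, span = c(6800, 300))
  ex <- build_exposures(ind, climate, ens, n_draws = 50, seed = 14)
  expect_equal(ex$temp, ind$true_temp, tolerance = 1e-12)
  expect_equal(ex$precip, ind$true_precip, tolerance = 1e-12)
  expect_equal(ex$kde_uncorrected, ind$true_population, tolerance = 1e-12)
})
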
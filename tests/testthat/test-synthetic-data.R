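test_that("zero-wiggle calibration curve is the identity map", {
  cc <- make_calibration_curve(0, 1000, 0, seed = 1)
  expect_equal(cc$mu, cc$cal_bp)
  expect_true(all(cc$sigma == 10))
  expect_true(all(diff(cc$cal_bp) > 0))
})

test_that("curve wiggle is smooth, bounded, and the grid is monotone", {
  devs <- vapply(1:100, function(s) {
    cc <- make_calibration_curve(0, 7000, 30, seed = s)
    max(abs(cc$mu - cc$cal_bp))
  }, numeric(1))
  expect_true(all(devs <= 3 * 30))
  cc <- make_calibration_curve(0, 7000, 30, seed = 1)
  expect_true(all(diff(cc$cal_bp) > 0))
  expect_true(all(cc$sigma > 0))
  # wiggle is approximately zero-mean
  expect_lt(abs(mean(cc$mu - cc$cal_bp)), 15)
})

test_that("inverted range and negative wiggle are rejected", {
  expect_error(make_calibration_curve(1000, 0, 30), "year_min")
  expect_error(make_calibration_curve(0, 1000, -5), "non-negative")
})

test_that("climate AR(1) structure matches its coefficient", {
  long <- simulate_climate_fields(lats = -10, lons = -75,
                                  year_range = c(6000, 0), step = 20,
                                  ar = 0, seed = 3)
  x <- long$values$temp[1, ]
  r0 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r0), 0.1)

  pers <- simulate_climate_fields(lats = -10, lons = -75,
                                  year_range = c(6000, 0), step = 20,
                                  ar = 0.9, seed = 3)
  y <- pers$values$temp[1, ]
  expect_gt(cor(y[-1], y[-length(y)]), 0.8)
})

test_that("zero innovations give constant series and precipitation stays non-negative", {
  const <- simulate_climate_fields(innovation_sd = c(temp = 0,
                                                     temp_seasonality = 0,
                                                     precip = 0,
                                                     precip_seasonality = 0),
                                   seed = 5)
  for (v in climate_vars())
    expect_true(all(apply(const$values[[v]], 1, sd) == 0))
  f <- simulate_climate_fields(seed = 6)
  expect_true(all(f$values$precip >= 0))
  expect_error(simulate_climate_fields(lats = numeric(0)), "empty grid")
})

test_that("simulated death years follow the population curve", {
  curve <- identity_curve(sigma = 10)
  pc <- list(years = seq(0, 7000, by = 10),
             density = rep(1, 701))
  d <- simulate_dates(pc, n_per_zone = c(coastal = 2000,
                                         "mid-elevation" = 1,
                                         highland = 1),
                      curve = curve, error_sd = 20, seed = 2)
  yrs <- d$true_year[d$lab_id |> startsWith("CO")]
  h <- table(cut(yrs, breaks = seq(0, 7000, length.out = 11)))
  expect_gt(chisq.test(h)$p.value, 0.01)
})

test_that("point-mass population curve yields the expected mean 14C age", {
  curve <- identity_curve(sigma = 10)
  pc <- list(years = seq(0, 7000, by = 10),
             density = as.numeric(seq(0, 7000, by = 10) == 3000))
  d <- simulate_dates(pc, n_per_zone = 2000, curve = curve, error_sd = 20,
                      seed = 4)
  co <- d[startsWith(d$lab_id, "CO") & !d$marine, ]
  expect_lt(abs(mean(co$age) - 3000), 1)

  exact <- simulate_dates(pc, n_per_zone = 50, curve = curve, error_sd = 0,
                          seed = 4, marine_frac = 0)
  expect_equal(exact$age, exact$true_year)
  expect_error(simulate_dates(pc, n_per_zone = 0, curve = curve),
               "positive")
})

test_that("noiseless single-covariate truth gives an exactly linear response", {
  climate <- simulate_climate_fields(seed = 8)
  ens <- flat_ensemble()
  truth <- default_truth(effect_shares = c(precip = 1), noise_sd = 0)
  ind <- simulate_individuals(200, climate, ens, truth, window_width = 0,
                              seed = 9, dated_fraction = 0,
                              frac_under5 = 0, frac_bad_cn = 0,
                              frac_colonial = 0, missing_d15N = 0,
                              missing_d13C = 0)
  # d15N = per-zone intercept + b * precip exactly
  fit <- lm(d15N ~ zone + true_precip, data = ind)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("individual records are complete, zoned, and windows contain the true year", {
  b <- shared_bundle()
  ind <- simulate_individuals(500, b$climate, b$ensembles, default_truth(),
                              window_width = 200, curve = b$curve,
                              seed = 10)
  expect_equal(nrow(ind), 500)
  expect_true(all(ind$zone %in% zones()))
  expect_true(all(ind$date_min <= ind$true_year &
                    ind$true_year <= ind$date_max))
  expect_true(all(ind$date_max - ind$date_min <= 200))
  expect_error(simulate_individuals(10, b$climate, b$ensembles,
                                    default_truth(), window_width = -1),
               "non-negative")
})

test_that("empirical variance shares match the intended effect shares", {
  climate <- simulate_climate_fields(seed = 11)
  ens <- flat_ensemble()
  # a two-bump single fit so the population component has variance
  grid <- seq(0, 7000, by = 20)
  dens <- dnorm(grid, 1500, 600) + 0.7 * dnorm(grid, 4500, 700)
  fits <- matrix(dens / paleodiet:::trapz(grid, dens), nrow = 1)
  ens <- population_ensemble("coastal", grid, fits, bandwidth = 50)
  ens <- list("coastal" = ens, "mid-elevation" = ens, "highland" = ens)
  truth <- default_truth()
  ind <- simulate_individuals(10000, climate, ens, truth, window_width = 0,
                              seed = 12, dated_fraction = 0,
                              missing_d15N = 0, missing_d13C = 0)
  zs <- data.frame(
    temp = scale(ind$true_temp)[, 1],
    temp_seasonality = scale(ind$true_temp_seasonality)[, 1],
    precip = scale(ind$true_precip)[, 1],
    precip_seasonality = scale(ind$true_precip_seasonality)[, 1],
    population = scale(ind$true_population)[, 1])
  zs$interaction <- scale(zs$temp * zs$precip)[, 1]
  comp_var <- vapply(names(truth$effect_shares), function(j)
    var(sqrt(truth$effect_shares[[j]]) * truth$scale * zs[[j]]),
    numeric(1))
  signal <- as.matrix(zs[names(truth$effect_shares)]) %*%
    (sqrt(truth$effect_shares) * truth$scale)
  noise <- ind$d15N - truth$baseline_d15N[ind$zone] - as.numeric(signal)
  total <- sum(comp_var) + var(noise)
  shares <- comp_var / total
  expect_true(all(abs(shares - truth$effect_shares) < 0.05))
  expect_lt(abs(var(noise) / total - truth$noise_share), 0.05)
})

test_that("generation is seed-deterministic and seeds differ", {
  a <- simulate_climate_fields(seed = 13)
  b <- simulate_climate_fields(seed = 13)
  c <- simulate_climate_fields(seed = 14)
  expect_identical(a$values$temp, b$values$temp)
  expect_false(identical(a$values$temp, c$values$temp))
})

test_that("bundle files round-trip through the module's own readers", {
  b <- shared_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  rt <- read_bundle(dir)
  expect_equal(rt$individuals$d15N, b$individuals$d15N, tolerance = 1e-12)
  expect_equal(rt$individuals$id, b$individuals$id)
  expect_equal(rt$dates$age, b$dates$age, tolerance = 1e-12)
  expect_equal(rt$curve$mu, b$curve$mu, tolerance = 1e-5)
  expect_equal(rt$climate$values$precip, b$climate$values$precip,
               tolerance = 1e-12)
  expect_equal(rt$truth$effect_shares, b$truth$effect_shares)
})
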
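test_that("generation is seed-explicit and deterministic", {
  cfg <- sim_config(n_specimens = 40L, views = c(ventral = 369))
  expect_error(simulate_localities(cfg), "seed")
  expect_error(simulate_hyena_dataset(cfg), "seed")
  d1 <- simulate_hyena_dataset(cfg, seed = 9)
  d2 <- simulate_hyena_dataset(cfg, seed = 9)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$density$samples, d2$density$samples)
  expect_identical(d1$landmarks$ventral$configs[[5]]$coords,
                   d2$landmarks$ventral$configs[[5]]$coords)
  d3 <- simulate_hyena_dataset(cfg, seed = 10)
  expect_false(identical(d1$records$lon, d3$records$lon))
})

test_that("zero specimens yield an empty record table", {
  recs <- simulate_localities(sim_config(n_specimens = 0L), seed = 1)
  expect_equal(nrow(recs), 0L)
})

test_that("cluster counts stay within binomial 99% bounds", {
  cfg <- sim_config()
  recs <- simulate_localities(cfg, seed = 13)
  n <- nrow(recs)
  w <- cfg$cluster_weights / sum(cfg$cluster_weights)
  for (cl in names(w)) {
    k <- sum(recs$cluster == cl)
    expect_gte(k, stats::qbinom(0.005, n, w[[cl]]))
    expect_lte(k, stats::qbinom(0.995, n, w[[cl]]))
  }
  # the default reproduces the study's sex stratification exactly
  expect_equal(as.vector(sex_counts(recs)), c(121L, 125L, 86L))
})

test_that("degenerate variogram settings behave as stated", {
  # nugget-only: no spatial structure, first-lag semivariance = variance
  cfg <- sim_config(n_density_samples = 150L,
                    dens_variogram = variogram_model(nugget = 0.5,
                                                     psill = 0, range = 1,
                                                     shape = 1.5))
  fld <- simulate_density_field(cfg, seed = 17)
  z <- log(fld$samples$density)
  emp <- empirical_semivariogram(fld$samples$lon, fld$samples$lat, z,
                                 n_lags = 8)
  expect_equal(emp$semivariance[1], stats::var(z), tolerance = 0.35)

  # zero-variance model: a constant field
  cfg0 <- sim_config(n_density_samples = 20L,
                     dens_variogram = variogram_model(nugget = 1e-12,
                                                      psill = 0,
                                                      range = 1,
                                                      shape = 1.5))
  fld0 <- simulate_density_field(cfg0, seed = 19)
  expect_lt(diff(range(log(fld0$samples$density))), 1e-4)
})

test_that("field marginals match the target lognormal", {
  true <- variogram_model(nugget = 0.3, psill = 0.45, range = 2,
                          shape = 1.5)
  cfg <- sim_config(n_density_samples = 500L, dens_variogram = true,
                    dens_meanlog = log(0.07))
  fld <- simulate_density_field(cfg, seed = 23)
  z <- log(fld$samples$density)
  ks <- stats::ks.test(z, "pnorm", mean = log(0.07),
                       sd = sqrt(0.3 + 0.45))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("noise-free, effect-free landmarks have the base size exactly", {
  cfg <- sim_config(n_specimens = 12L, views = c(ventral = 369),
                    dimorphism = 1, density_effect = 0,
                    trend_fun = function(lon, lat) 0,
                    size_noise = 0, digit_noise = 0)
  recs <- simulate_localities(cfg, seed = 29)
  lm_v <- simulate_landmarks(cfg, recs,
                             factor(rep("low", 12),
                                    levels = c("low", "high")),
                             view = "ventral", seed = 31)
  cs <- vapply(lm_v$configs, centroid_size, numeric(1))
  expect_equal(cs, rep(369, 12), tolerance = 1e-9)
})

test_that("the generated dimorphism matches its target at large n", {
  cfg <- sim_config(n_specimens = 3000L, views = c(ventral = 369))
  recs <- simulate_localities(cfg, seed = 37)
  dens <- factor(sample(c("low", "high"), 3000, TRUE),
                 levels = c("low", "high"))
  lm_v <- simulate_landmarks(cfg, recs, dens, view = "ventral", seed = 41)
  f <- lm_v$true_size[recs$sex == "female"]
  m <- lm_v$true_size[recs$sex == "male"]
  expect_equal(mean(f) / mean(m), 1.012, tolerance = 2e-3)
})

test_that("GPA recovers generating sizes from simulated landmarks", {
  cfg <- sim_config(n_specimens = 60L, views = c(ventral = 369))
  ds <- simulate_hyena_dataset(cfg, seed = 43)
  fit <- gpa_align(ds$landmarks$ventral$configs)
  # under default effects the generating sizes span only ~2% of the mean,
  # so the attainable correlation is a little below the wide-size-range
  # benchmark of test-morphometrics
  expect_gt(cor(unname(fit$centroid_sizes),
                ds$landmarks$ventral$true_size), 0.995)
})

test_that("kriging the simulated samples beats the global-mean predictor", {
  cfg <- sim_config(n_specimens = 120L, views = c(ventral = 369))
  recs <- simulate_localities(cfg, seed = 47)
  fld <- simulate_density_field(cfg, seed = 49, query_lon = recs$lon,
                                query_lat = recs$lat)
  s <- fld$samples
  emp <- empirical_semivariogram(s$lon, s$lat, log(s$density), n_lags = 12)
  vg <- fit_variogram(emp, shape = 1.5)
  kr <- universal_krige(s$lon, s$lat, log(s$density), vg, drift_order = 1,
                        query_lon = recs$lon, query_lat = recs$lat,
                        clip_negative = FALSE)
  truth <- log(fld$truth)
  mse_krige <- mean((kr$predictions$estimate - truth)^2)
  mse_mean <- mean((mean(log(s$density)) - truth)^2)
  expect_lt(mse_krige, mse_mean)
})

test_that("written datasets are read back consistently", {
  cfg <- sim_config(n_specimens = 15L, views = c(ventral = 369))
  ds <- simulate_hyena_dataset(cfg, seed = 53)
  dir <- withr::local_tempdir()
  paths <- write_sim_dataset(ds, dir)
  cfgs <- read_tps(paths$tps_ventral, fixed = ds$landmarks$ventral$template$fixed)
  expect_length(cfgs, 15L)
  expect_equal(cfgs[[3]]$coords, ds$landmarks$ventral$configs[[3]]$coords,
               tolerance = 1e-10)
  sl <- read_slider_table(paths$sliders_ventral)
  expect_equal(as.data.frame(sl),
               as.data.frame(ds$landmarks$ventral$template$sliders))
  sp <- read_specimen_table(paths$specimens)
  expect_equal(nrow(sp), 15L)
  g <- read_ascii_grid(paths$grid_temperature)
  expect_equal(g$values, ds$grids$temperature$values, tolerance = 1e-6)
})
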
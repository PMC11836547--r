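test_that("landscape and trajectory configurations validate their inputs", {
  expect_error(landscape_config(1, 10), "n_rows")
  expect_error(landscape_config(10, 10, fine_per_coarse = 0), "fine_per_coarse")
  expect_error(climate_trajectory(step = 0), "spacing")
  expect_error(climate_trajectory(t_start = 500, t_end = 12000), "before")
})

test_that("climate generation is deterministic and exact without noise", {
  land <- landscape_config(6, 8, fine_per_coarse = 2, seed = 5)
  traj <- climate_trajectory(t_start = 12000, t_end = 11000, step = 250,
                             noise_sd = 0, precip_noise_sd = 0)
  a <- gen_climate_series(land, traj, n_years = 4, seed = 3)
  b <- gen_climate_series(land, traj, n_years = 4, seed = 3)
  expect_identical(a, b)
  # zero noise: every year identical, covariates a pure function of
  # (time, position)
  sl <- a[[1]]
  expect_equal(sl$seasonal_temp[, , 1, 1], sl$seasonal_temp[, , 1, 4])
  # spacing invariant
  times <- vapply(a, `[[`, numeric(1), "time_bp")
  expect_true(all(diff(times) == -250))
  # noisy runs with different seeds differ
  c1 <- gen_climate_series(land, climate_trajectory(noise_sd = 1), 4, seed = 1)
  c2 <- gen_climate_series(land, climate_trajectory(noise_sd = 1), 4, seed = 2)
  expect_false(identical(c1[[1]]$tmin_winter, c2[[1]]$tmin_winter))
})

test_that("configured warming amplitude is recovered from the slices", {
  land <- landscape_config(20, 20, seed = 2)
  traj <- climate_trajectory(t_start = 12000, t_end = 9750, step = 250,
                             amplitude = 8, changepoint = 11500,
                             transition = 500, south_damping = 0.5,
                             noise_sd = 0.6)
  slices <- gen_climate_series(land, traj, n_years = 30, seed = 4)
  times <- vapply(slices, `[[`, numeric(1), "time_bp")
  cold <- slices[[which(times == 12000)]]
  warm <- slices[[which(times == 10000)]]
  observed <- mean(warm$tmin_winter) - mean(cold$tmin_winter)
  # expected warming averaged over rows given the polar-amplification
  # damping profile
  rowfrac <- (seq_len(20) - 1) / 19
  expected <- 8 * mean(1 - 0.5 * rowfrac)
  tol <- 4 * 0.6 / sqrt(20 * 20 * 30)
  expect_lt(abs(observed - expected), tol + 0.05)
})

test_that("trend regression on generated slices recovers the trajectory", {
  land <- landscape_config(10, 10, seed = 3)
  traj <- climate_trajectory(t_start = 11000, t_end = 9000, step = 250,
                             amplitude = 8, changepoint = 11500,
                             transition = 500, south_damping = 0,
                             noise_sd = 0.5)
  # all slices are past the ramp: a linear fit on time must be ~flat
  slices <- gen_climate_series(land, traj, n_years = 20, seed = 9)
  times <- vapply(slices, `[[`, numeric(1), "time_bp")
  means <- vapply(slices, function(s) mean(s$tmin_winter), numeric(1))
  fit <- lm(means ~ times)
  expect_lt(abs(coef(fit)[2]), 1e-3)
})

test_that("elevation downscaling matches the lapse-rate formula", {
  land <- landscape_config(4, 4, fine_per_coarse = 2, seed = 1)
  traj <- climate_trajectory(noise_sd = 0.3)
  sl <- gen_climate_series(land, traj, n_years = 3, seed = 2)[[1]]
  # identity: equal elevations leave the slice unchanged
  flat <- matrix(150, 8, 8)
  out <- downscale_elevation(sl, flat, coarse_elevation = matrix(150, 4, 4))
  expect_equal(out$tmin_winter, broadcast_to_fine(sl$tmin_winter, 2))
  expect_equal(out$precip_total, broadcast_to_fine(sl$precip_total, 2))
  # closed form: 1000 m above the coarse cell at 6.5 deg/km -> 6.5 C colder
  up <- matrix(1000, 8, 8)
  out2 <- downscale_elevation(sl, up, coarse_elevation = matrix(0, 4, 4),
                              lapse_rate = 6.5)
  expect_equal(out2$tmin_winter,
               broadcast_to_fine(sl$tmin_winter, 2) - 6.5, tolerance = 1e-12)
  # random elevation field: per-cell brute-force formula
  set.seed(7)
  fe <- matrix(runif(64, 0, 2000), 8, 8)
  ce <- matrix(runif(16, 0, 500), 4, 4)
  out3 <- downscale_elevation(sl, fe, coarse_elevation = ce, lapse_rate = 5)
  expected <- broadcast_to_fine(sl$tmin_winter, 2) -
    5 * (fe - broadcast_to_fine(ce, 2)) / 1000
  expect_equal(out3$tmin_winter, expected, tolerance = 1e-12)
  # non-nested grids rejected
  expect_error(downscale_elevation(sl, matrix(0, 7, 8)), "nest")
})

test_that("true occupancy respects fitness limits and reproducibility", {
  w <- tiny_world(n_slices = 4)
  sp <- beechlike_species()
  k <- small_kernel()
  # fitness zero everywhere -> init fails with the empty-map error
  dead <- virtual_species("none", gdd_req = 1e6, gdd_slope = 10)
  expect_error(gen_true_occupancy(dead, w$slices, k, w$land, seed = 1),
               class = "paleoshift_empty_map")
  t1 <- gen_true_occupancy(sp, w$slices, k, w$land, seed = 5)
  t2 <- gen_true_occupancy(sp, w$slices, k, w$land, seed = 5)
  expect_identical(t1$occupancy, t2$occupancy)
  # occupied area cannot exceed the suitable area, per slice
  for (i in seq_along(w$slices)) {
    suit_fine <- broadcast_to_fine(t1$prob_series[[i]]$values > 0,
                                   w$land$fine_per_coarse)
    expect_true(all(!t1$occupancy[[i]]$occupied | suit_fine))
  }
})

test_that("pollen archive counts follow the configured detection model", {
  land <- landscape_config(6, 6, seed = 2)
  occ <- matrix(TRUE, 6, 6)
  none <- matrix(FALSE, 6, 6)
  times <- c(1000, 750)
  # zero detection + empty occupancy -> all focal counts zero
  arch0 <- gen_pollen_archive(list(Fagus = list(none, none)), times, land,
                              pollen_plan(n_sites = 30,
                                          detection = list(occupied = 0.3,
                                                           unoccupied = 0)),
                              seed = 4)
  expect_true(all(arch0$count_Fagus == 0))
  expect_equal(arch0$total_count,
               arch0$count_Fagus + arch0$count_other)
  # occupied everywhere with expected abundance 0.1: Monte-Carlo mean of the
  # observed relative abundance matches the binomial expectation
  arch1 <- gen_pollen_archive(list(Fagus = list(occ, occ)), times, land,
                              pollen_plan(n_sites = 400, p_sample = 1,
                                          detection = list(occupied = 0.1,
                                                           unoccupied = 0)),
                              seed = 5)
  rel <- arch1$count_Fagus / arch1$total_count
  expect_lt(abs(mean(rel) - 0.1), 3 * sd(rel) / sqrt(length(rel)))
  # marine fraction
  arch2 <- gen_pollen_archive(list(Fagus = list(occ, occ)), times, land,
                              pollen_plan(n_sites = 100,
                                          marine_fraction = 0.2),
                              seed = 6)
  n_marine <- length(unique(arch2$site_id[
    arch2$depositional_env == "marine"]))
  expect_gte(n_marine, qbinom(0.001, 100, 0.2))
  expect_lte(n_marine, qbinom(0.999, 100, 0.2))
  # invalid detection probabilities rejected
  expect_error(gen_pollen_archive(list(Fagus = list(occ)), 1000, land,
                                  pollen_plan(detection = list(
                                    occupied = 1.2, unoccupied = 0)),
                                  seed = 1),
               "detection")
})

test_that("archive marginals match the configured count and age models", {
  land <- landscape_config(8, 8, seed = 3)
  occ <- matrix(TRUE, 8, 8)
  plan <- pollen_plan(n_sites = 275, p_sample = 1)
  arch <- gen_pollen_archive(list(Fagus = list(occ, occ, occ, occ)),
                             c(2000, 1750, 1500, 1250), land, plan, seed = 8)
  expect_gte(nrow(arch), 1000)
  ks_age <- suppressWarnings(
    ks.test(arch$age_uncertainty_yr, plnorm, plan$age_meanlog,
            plan$age_sdlog))
  expect_gt(ks_age$p.value, 0.01)
  # counts are rounded lognormals; compare on the log scale with a normal
  ks_count <- suppressWarnings(
    ks.test(log(arch$total_count), pnorm, plan$count_meanlog,
            plan$count_sdlog))
  expect_gt(ks_count$p.value, 0.01)
})
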
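test_that("seasonal feature tables unroll cell-by-year seasonal fields", {
  land <- landscape_config(3, 2, seed = 1)
  traj <- climate_trajectory(noise_sd = 0.4, precip_noise_sd = 10)
  sl <- gen_climate_series(land, traj, n_years = 4, seed = 2)[[1]]
  tab <- seasonal_features(sl)
  expect_equal(nrow(tab), 6 * 4)
  expect_equal(names(tab)[-(1:2)],
               c("T_winter", "T_spring", "T_summer", "T_autumn",
                 "P_winter", "P_spring", "P_summer", "P_autumn"))
  # hand-assembled check for one cell/year: cell 5 = (row 2, col 3 of a
  # 3 x 2 grid) -> row 2, col 3? grids are column-major: cell 5 is row 2,
  # col 2
  expect_equal(tab$T_summer[tab$cell == 5 & tab$year == 3],
               sl$seasonal_temp[2, 2, 3, 3])
  expect_equal(tab$P_winter[tab$cell == 1 & tab$year == 4],
               sl$seasonal_precip[1, 1, 1, 4])
  # constant climate -> identical rows
  sl0 <- gen_climate_series(land, climate_trajectory(noise_sd = 0,
                                                     precip_noise_sd = 0,
                                                     temp_gradient = 0,
                                                     precip_gradient = 0,
                                                     amplitude = 0),
                            n_years = 3, seed = 3)[[1]]
  tab0 <- seasonal_features(sl0)
  expect_equal(max(apply(tab0[, -(1:2)], 2, sd)), 0)
})

test_that("delta/ratio bias correction is exact on constant biases", {
  land <- landscape_config(4, 4, seed = 5)
  traj <- climate_trajectory(noise_sd = 0, precip_noise_sd = 0)
  sim <- gen_climate_series(land, traj, n_years = 3, seed = 6)
  obs_ref <- sim[[length(sim)]]
  # identity: simulated reference equals observations
  same <- bias_correct(sim, sim[[length(sim)]], obs_ref)
  expect_equal(same[[1]]$seasonal_temp, sim[[1]]$seasonal_temp)
  # constant +2 C simulation bias removed exactly
  biased_ref <- obs_ref
  biased_ref$seasonal_temp <- obs_ref$seasonal_temp + 2
  sim_b <- lapply(sim, function(s) {
    s$seasonal_temp <- s$seasonal_temp + 2; s
  })
  fixed <- bias_correct(sim_b, biased_ref, obs_ref)
  expect_equal(fixed[[1]]$seasonal_temp, sim[[1]]$seasonal_temp,
               tolerance = 1e-10)
  # precipitation ratio rule: sim_ref 50, obs_ref 100, sim 30 -> 60
  s50 <- obs_ref; s50$seasonal_precip[] <- 50
  o100 <- obs_ref; o100$seasonal_precip[] <- 100
  s30 <- obs_ref; s30$seasonal_precip[] <- 30
  out <- bias_correct(list(s30), s50, o100)
  expect_equal(out[[1]]$seasonal_precip[1, 1, 1, 1], 60)
  # mismatched reference windows rejected
  small <- gen_climate_series(landscape_config(3, 3, seed = 1), traj,
                              n_years = 3, seed = 2)[[1]]
  expect_error(bias_correct(sim, small, obs_ref), "overlap")
})

test_that("reference PCA projection is an isometry on isotropic data", {
  set.seed(11)
  X <- matrix(rnorm(900), 300, 3)
  colnames(X) <- c("T_winter", "T_spring", "T_summer")
  pr <- pca_reference(X, k = 3)
  P <- project(pr, X)
  d_orig <- dist(scale(X)[1:30, ])
  d_proj <- dist(P[1:30, ])
  expect_equal(as.numeric(d_proj), as.numeric(d_orig), tolerance = 1e-8)
  # identical rows map to identical coordinates under shared loadings
  Y <- X[c(1, 1, 2), ]
  PY <- project(pr, Y)
  expect_equal(PY[1, ], PY[2, ])
  # variance concentrated on one axis -> PC1 dominates
  Z <- cbind(rnorm(300, sd = 30), rnorm(300, sd = 0.1), rnorm(300, sd = 0.1))
  colnames(Z) <- colnames(X)
  przz <- pca_reference(Z, k = 3)
  expect_gt(przz$sdev[1]^2 / sum(przz$sdev^2), 0.3)
  # raw (unstandardised) dominance checked via covariance directly
  ev <- eigen(cov(Z))$values
  expect_gt(ev[1] / sum(ev), 0.99)
  # degenerate reference rejected
  Z2 <- Z; Z2[, 2] <- 1
  expect_error(pca_reference(Z2, k = 3), "rank-deficient")
})

test_that("bootstrap hypervolumes recover the analytic normal volume", {
  set.seed(21)
  X <- matrix(rnorm(3000), 1000, 3)
  expect_error(bootstrap_hypervolume(X[c(1, 1, 1, 1), ], n_boot = 1),
               "degenerate")
  expect_warning(bootstrap_hypervolume(X[1:20, ], n_boot = 1, seed = 1),
                 "fewer than 50")
  h1 <- bootstrap_hypervolume(X, n_boot = 1, cloud_size = 500, seed = 2)
  h2 <- bootstrap_hypervolume(X, n_boot = 1, cloud_size = 500, seed = 2)
  expect_identical(h1[[1]]$cloud, h2[[1]]$cloud)
  # volume of the 95% region of a 3-D standard normal: 4/3 pi r^3 with
  # r^2 the 0.95 chi-square quantile
  hv <- bootstrap_hypervolume(X, n_boot = 5, cloud_size = 1500, seed = 3)
  vol <- mean(vapply(hv, `[[`, numeric(1), "volume"))
  analytic <- 4 / 3 * pi * qchisq(0.95, 3)^1.5
  expect_lt(abs(vol - analytic) / analytic, 0.15)
})

test_that("hypervolume overlap matches a grid-integration oracle", {
  set.seed(31)
  A <- bootstrap_hypervolume(matrix(rnorm(900), 300, 3), n_boot = 1,
                             cloud_size = 1500, seed = 32)[[1]]
  B <- bootstrap_hypervolume(sweep(matrix(rnorm(900), 300, 3), 2,
                                   c(1, 0, 0), "+"),
                             n_boot = 1, cloud_size = 1500, seed = 33)[[1]]
  # self-overlap
  expect_gt(overlap_sorensen(A, A), 0.95)
  # disjoint clouds separated by ~10 bandwidths
  C <- B
  C$kernel_points <- sweep(B$kernel_points, 2, c(50, 0, 0), "+")
  C$cloud <- sweep(B$cloud, 2, c(50, 0, 0), "+")
  expect_lt(overlap_sorensen(A, C), 0.01)
  # delta = 1 shifted pair against direct numerical integration
  got <- overlap_sorensen(A, B)
  ora <- oracle_overlap_grid(A, B, n_grid = 45)
  expect_lt(abs(got - ora), 0.05)
  bad <- A; bad$dim <- 2; bad$kernel_points <- A$kernel_points[, 1:2]
  expect_error(overlap_sorensen(bad, B), "dimension")
})

test_that("overlap estimator error shrinks like one over root cloud size", {
  set.seed(41)
  base <- matrix(rnorm(900), 300, 3)
  shift <- sweep(matrix(rnorm(900), 300, 3), 2, c(1, 0, 0), "+")
  ses <- vapply(c(250, 1000), function(cs) {
    reps <- vapply(1:12, function(r) {
      A <- bootstrap_hypervolume(base, 1, cloud_size = cs,
                                 seed = 1000 + r)[[1]]
      B <- bootstrap_hypervolume(shift, 1, cloud_size = cs,
                                 seed = 2000 + r)[[1]]
      overlap_sorensen(A, B)
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  slope <- (log(ses[2]) - log(ses[1])) / (log(1000) - log(250))
  # bootstrap-sample noise adds a floor, so the slope is bounded by the
  # Monte-Carlo rate rather than matching it exactly
  expect_lt(slope, 0)
  expect_gt(slope, -1)
})

test_that("dissimilarity separates self, shifted and disjoint periods", {
  set.seed(51)
  mkfeat <- function(shift) {
    X <- matrix(rnorm(1000 * 3), 1000, 3)
    X[, 1] <- X[, 1] + shift
    colnames(X) <- c("T_winter", "T_summer", "P_summer")
    as.data.frame(X)
  }
  ref <- mkfeat(0)
  d_self <- dissimilarity(mkfeat(0), ref, n_boot = 6, cloud_size = 500,
                          seed = 52)
  expect_lt(d_self$mean, 0.15)
  expect_equal(d_self$n_pairs, 36)
  d_far <- dissimilarity(mkfeat(30), ref, n_boot = 4, cloud_size = 400,
                         seed = 53)
  expect_gt(d_far$mean, 0.95)
  # monotone over an increasing shift sweep
  means <- vapply(c(0, 1, 2, 4), function(s)
    dissimilarity(mkfeat(s), ref, n_boot = 4, cloud_size = 400,
                  seed = 54)$mean, numeric(1))
  expect_true(all(diff(means) > 0))
  # symmetry in distribution: swapping focal and reference moves the mean
  # by less than two Monte-Carlo sds
  d_ab <- dissimilarity(mkfeat(1.5), ref, n_boot = 6, cloud_size = 500,
                        seed = 55)
  d_ba <- dissimilarity(ref, mkfeat(1.5), n_boot = 6, cloud_size = 500,
                        seed = 56)
  expect_lt(abs(d_ab$mean - d_ba$mean),
            2 * sqrt(d_ab$sd^2 / d_ab$n_pairs + d_ba$sd^2 / d_ba$n_pairs) +
              0.05)
})

test_that("Mahalanobis novelty equals the brute-force double loop", {
  set.seed(61)
  R <- matrix(rnorm(200), 50, 4) %*% diag(c(1, 2, 0.5, 1))
  F <- matrix(rnorm(48), 12, 4)
  got <- mahalanobis_novelty(F, R)
  ora <- bf_mahalanobis_min(F, R, cov(R))
  expect_equal(got, ora, tolerance = 1e-8)
  # a focal vector inside the pool has distance zero
  expect_equal(mahalanobis_novelty(R[3, , drop = FALSE], R)[1], 0,
               tolerance = 1e-8)
  # identity covariance reduces to minimum Euclidean distance
  set.seed(62)
  E <- matrix(rnorm(4000), 1000, 4)  # empirical cov ~ identity
  f1 <- matrix(c(10, 0, 0, 0), 1)
  d_euc <- min(sqrt(rowSums(sweep(E, 2, f1)^2)))
  expect_equal(mahalanobis_novelty(f1, E)[1], d_euc, tolerance = 0.15)
})
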
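test_that("kernel discretisation integrates the continuous density", {
  # degenerate point kernel: radius 0 puts all mass at the origin
  k0 <- discretize_kernel("exponential_power", list(a = 1, b = 1),
                          radius = 0)
  expect_equal(k0$short_kernel, matrix(1, 1, 1))
  # isotropy: symmetric under 90-degree rotation and reflection
  k <- discretize_kernel("exponential_power", list(a = 600, b = 0.8),
                         radius = 4)
  m <- k$short_kernel
  expect_equal(m, t(m))
  expect_equal(m, m[rev(seq_len(nrow(m))), ])
  expect_equal(sum(m), 1)
  # exponential kernel with mean 1000 m (a = 500): mass within 2 cells of
  # the matrix matches the continuous CDF at the matching radius
  ke <- discretize_kernel("exponential_power", list(a = 500, b = 1),
                          radius = 8, cell_size = 500)
  off <- seq(-8, 8) * 500
  dist <- sqrt(outer(off^2, off^2, "+"))
  got_mass <- sum(ke$short_kernel[dist <= 1250])
  norm_const <- integrate(function(r) 2 * pi * r * exp(-r / 500), 0, Inf)$value
  cdf <- integrate(function(r) 2 * pi * r * exp(-r / 500), 0, 1250)$value /
    norm_const
  expect_lt(abs(got_mass - cdf), 0.02)
  # 2Dt requires integrability
  expect_error(discretize_kernel("twodt", list(a = 500, b = 0.8)),
               "integrable")
  # tail sampler produces distances beyond the truncation radius
  expect_true(!is.null(ke$ld_sampler))
  set.seed(1)
  d <- ke$ld_sampler(200)
  expect_true(all(d >= 8.5 * 500))
})

test_that("threshold/rescale maps suitability to colonisation probability", {
  m <- structure(list(values = matrix(c(0.1, 0.3, 0.6, 0.9), 2, 2),
                      species = "x", time_bp = 0, threshold = 0.3,
                      v_max = 0.9, rescaled = FALSE),
                 class = "suitability_map")
  out <- threshold_rescale(m)
  expect_equal(out$values[1, 1], 0)   # below tau
  expect_equal(out$values[2, 1], 0)   # exactly tau -> zero
  expect_equal(out$values[1, 2], 0.5) # (0.6-0.3)/(0.9-0.3)
  expect_equal(out$values[2, 2], 1)   # at v_max
  all_low <- m; all_low$values[] <- 0.1
  expect_equal(threshold_rescale(all_low)$values, matrix(0, 2, 2))
  expect_error(threshold_rescale(m, tau = 0.95, v_max = 0.9),
               class = "paleoshift_empty_map")
})

test_that("occupancy initialisation defers past empty slices", {
  land <- landscape_config(4, 4, fine_per_coarse = 2, seed = 1)
  zero <- structure(list(values = matrix(0, 4, 4), species = "x",
                         time_bp = 1000, rescaled = TRUE),
                    class = "suitability_map")
  one <- zero; one$values[2, 3] <- 0.8; one$time_bp <- 750
  init <- init_occupancy(list(zero, one), land)
  expect_equal(init$start_index, 2)
  # exactly the fine cells of that coarse cell are occupied
  expect_equal(sum(init$occ$occupied), 4)
  expect_true(all(which(init$occ$occupied, arr.ind = TRUE)[, 1] %in% 3:4))
  expect_error(init_occupancy(list(zero, zero), land),
               class = "paleoshift_empty_map")
})

test_that("a zero-probability map never gains occupancy", {
  occ <- paleoshift:::new_occupancy_grid(matrix(FALSE, 8, 8), 0)
  occ$occupied[4, 4] <- TRUE
  k <- rook_kernel()
  set.seed(2)
  out <- disperse_step(occ, matrix(0, 8, 8), k)
  expect_equal(out$occupied, occ$occupied)
})

test_that("deterministic rook kernel spreads as the BFS diamond", {
  n <- 41
  occ <- paleoshift:::new_occupancy_grid(matrix(FALSE, n, n), 0)
  occ$occupied[21, 21] <- TRUE
  p <- matrix(1, n, n)
  k <- rook_kernel()
  set.seed(3)
  for (s in 1:8) occ <- disperse_step(occ, p, k)
  expect_identical(occ$occupied, bf_diamond(n, n, 21, 21, 8))
})

test_that("migration collapses, saturates, and reproduces exactly", {
  land <- landscape_config(8, 8, fine_per_coarse = 2, seed = 4)
  full <- structure(list(values = matrix(1, 8, 8), species = "x",
                         time_bp = 1000, rescaled = TRUE),
                    class = "suitability_map")
  none <- full; none$values[] <- 0
  start <- full; start$values[] <- 0; start$values[4, 4] <- 1
  k <- small_kernel(radius = 2)
  # suitability 1 everywhere: colonised area non-decreasing to saturation
  series <- list(start, full, full, full)
  for (i in seq_along(series)) series[[i]]$time_bp <- 1000 - 250 * (i - 1)
  mig <- run_migration(series, k, land, years_per_slice = 40, seed = 5)
  areas <- vapply(mig$occupancy, function(o) sum(o$occupied), numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_equal(areas[length(areas)], 256)  # saturated
  # zero suitability after the start: collapse to empty
  crash <- list(start, none, none)
  for (i in seq_along(crash)) crash[[i]]$time_bp <- 1000 - 250 * (i - 1)
  mig2 <- run_migration(crash, k, land, years_per_slice = 10, seed = 6)
  expect_equal(sum(mig2$occupancy[[2]]$occupied), 0)
  # byte-identical on re-run with the same seed
  mig3 <- run_migration(series, k, land, years_per_slice = 40, seed = 5)
  expect_identical(mig$occupancy, mig3$occupancy)
  expect_error(run_migration(list(), k, land), "empty")
})

test_that("spread never outruns the kernel radius without long-distance events", {
  set.seed(7)
  for (rep in 1:100) {
    R <- sample(1:3, 1)
    nr <- sample(8:14, 1); nc <- sample(8:14, 1)
    km <- matrix(runif((2 * R + 1)^2)^2, 2 * R + 1, 2 * R + 1)
    km[sample(length(km), length(km) %/% 2)] <- 0
    if (sum(km) == 0) km[1, 1] <- 0.5
    k <- dispersal_kernel(km, normalize = FALSE, ld_probability = 0)
    occ <- paleoshift:::new_occupancy_grid(
      matrix(runif(nr * nc) < 0.2, nr, nc), 0)
    p <- matrix(runif(nr * nc), nr, nc)
    # 25 annual steps per scenario: every new colonisation stays inside the
    # Chebyshev dilation of the previous front
    for (s in 1:25) {
      nxt <- disperse_step(occ, p, k)
      if (any(occ$occupied)) {
        allowed <- bf_dilate(occ$occupied, R)
        expect_true(all(!nxt$occupied | allowed | occ$occupied))
      }
      occ <- nxt
    }
  }
})

test_that("Monte-Carlo front speed matches an independent simulator", {
  # strip geometry: left column seeded, establishment certain, fat-tailed
  # kernel without long-distance jumps
  nr <- 25; nc <- 46; steps <- 8
  k <- small_kernel(radius = 3)
  p <- matrix(1, nr, nc)
  front_of <- function(m) (max(col(m)[m]) - 1) / steps
  set.seed(8)
  oracle <- replicate(150, {
    occ <- matrix(FALSE, nr, nc); occ[, 1] <- TRUE
    front_of(oracle_disperse_run(occ, p, k$short_kernel, steps))
  })
  pkg <- replicate(60, {
    occ <- paleoshift:::new_occupancy_grid(matrix(FALSE, nr, nc), 0)
    occ$occupied[, 1] <- TRUE
    for (s in seq_len(steps)) occ <- disperse_step(occ, p, k)
    front_of(occ$occupied)
  })
  se <- sqrt(var(oracle) / length(oracle) + var(pkg) / length(pkg))
  expect_lt(abs(mean(pkg) - mean(oracle)), qnorm(0.975) * se + 1e-9)
})

test_that("raising colonisation probability cannot shrink colonisation", {
  # single coupled step: same occupancy, same seed, nested probabilities
  set.seed(9)
  k <- small_kernel(radius = 2)
  for (rep in 1:100) {
    occ <- paleoshift:::new_occupancy_grid(matrix(runif(100) < 0.2, 10, 10), 0)
    p1 <- matrix(runif(100, 0.05, 0.6), 10, 10)
    p2 <- pmin(p1 * 1.8, 1)
    seed <- sample.int(1e6, 1)
    o1 <- with(list(), { set.seed(seed); disperse_step(occ, p1, k) })
    o2 <- with(list(), { set.seed(seed); disperse_step(occ, p2, k) })
    expect_true(all(!o1$occupied | o2$occupied))
  }
})

test_that("long-distance events colonise beyond the short-kernel reach", {
  k <- discretize_kernel("exponential_power", list(a = 2000, b = 0.6),
                         radius = 2, cell_size = 500, ld_probability = 0.8,
                         target_mass = 0.5)
  n <- 61
  occ <- paleoshift:::new_occupancy_grid(matrix(FALSE, n, n), 0)
  occ$occupied[31, 31] <- TRUE
  p <- matrix(1, n, n)
  set.seed(10)
  jumped <- FALSE
  for (s in 1:40) {
    occ <- disperse_step(occ, p, k)
    d <- max(pmax(abs(row(occ$occupied) - 31), abs(col(occ$occupied) - 31))[
      occ$occupied])
    if (d > 2 * s) { jumped <- TRUE; break }
  }
  expect_true(jumped)
})

test_that("combining deciduous maps is the elementwise maximum", {
  a <- structure(list(values = matrix(runif(16), 4, 4), species = "A",
                      time_bp = 0, threshold = NA, v_max = NA,
                      rescaled = FALSE), class = "suitability_map")
  b <- a; b$values <- matrix(runif(16), 4, 4); b$species <- "B"
  out <- combine_deciduous(a, b)
  expected <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    expected[i, j] <- max(a$values[i, j], b$values[i, j])
  }
  expect_equal(out$values, expected)
  zero <- b; zero$values[] <- 0
  expect_equal(combine_deciduous(a, zero)$values, a$values)
  expect_equal(combine_deciduous(a, a)$values, a$values)
  wrong <- b; wrong$values <- matrix(0, 3, 3)
  expect_error(combine_deciduous(a, wrong), "mismatch")
})

test_that("coarsening matches a per-block any() scan", {
  set.seed(11)
  fine <- matrix(runif(24 * 36) < 0.07, 24, 36)
  got <- coarsen_occupancy(fine, 4)
  expected <- matrix(FALSE, 6, 9)
  for (i in 1:6) for (j in 1:9) {
    expected[i, j] <- any(fine[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)])
  }
  expect_identical(got, expected)
  expect_equal(sum(coarsen_occupancy(matrix(FALSE, 8, 8), 2)), 0)
  one <- matrix(FALSE, 8, 8); one[5, 2] <- TRUE
  expect_equal(sum(coarsen_occupancy(one, 2)), 1)
  expect_error(coarsen_occupancy(matrix(FALSE, 9, 8), 2), "nest")
})

test_that("dispersal stochasticity barely moves coarse-grid scores", {
  w <- tiny_world(nr = 20, nc = 20, f = 2, n_slices = 5, seed = 12)
  sp <- beechlike_species()
  k <- small_kernel()
  truth <- gen_true_occupancy(sp, w$slices, k, w$land, seed = 100)
  truth_last <- truth$presence[[length(w$slices)]]
  scores <- vapply(1:10, function(s) {
    mig <- run_migration(truth$prob_series, k, w$land,
                         years_per_slice = 250, seed = 200 + s)
    pred <- coarsen_occupancy(mig$occupancy[[length(w$slices)]],
                              w$land$fine_per_coarse)
    tp <- sum(pred & truth_last); fp <- sum(pred & !truth_last)
    fn <- sum(!pred & truth_last)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_lt(sd(scores), 0.05)
})
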
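# Small-world fixtures built in code.

# A climate slice with given covariate matrices (no seasonal arrays; enough
# for the suitability models).
slice_from_covariates <- function(tmin, gdd, precip, wb, time_bp = 0) {
  structure(list(time_bp = time_bp, tmin_winter = tmin, gdd = gdd,
                 precip_total = precip, water_balance_summer = wb),
            class = "climate_slice")
}

rand_covariate_slice <- function(nr = 10, nc = 10, seed = 1, time_bp = 0) {
  set.seed(seed)
  slice_from_covariates(
    tmin = matrix(runif(nr * nc, -20, 0), nr, nc),
    gdd = matrix(runif(nr * nc, 200, 2500), nr, nc),
    precip = matrix(runif(nr * nc, 300, 1200), nr, nc),
    wb = matrix(runif(nr * nc, -150, 50), nr, nc),
    time_bp = time_bp)
}

tiny_world <- function(nr = 16, nc = 16, f = 2, n_slices = 6, n_years = 8,
                       seed = 11, noise_sd = 0.5) {
  land <- landscape_config(nr, nc, fine_per_coarse = f, seed = seed)
  traj <- climate_trajectory(t_start = 12000,
                             t_end = 12000 - 250 * (n_slices - 1),
                             step = 250, noise_sd = noise_sd)
  slices <- gen_climate_series(land, traj, n_years = n_years)
  list(land = land, traj = traj, slices = slices,
       times = vapply(slices, `[[`, numeric(1), "time_bp"))
}

beechlike_species <- function() {
  virtual_species("Fagus", frost_t50 = -14, frost_slope = 1.5,
                  drought_w50 = -60, drought_slope = 15,
                  gdd_req = 900, gdd_slope = 100)
}

small_kernel <- function(radius = 3, ld = 0) {
  discretize_kernel("exponential_power", list(a = 400, b = 1),
                    radius = radius, cell_size = 500, ld_probability = ld)
}

# Deterministic 4-neighbour kernel: colonisation probability one to each
# rook neighbour.
rook_kernel <- function() {
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[2, 3] <- m[1, 2] <- m[3, 2] <- 1
  dispersal_kernel(m, normalize = FALSE, ld_probability = 0)
}

# A small archive with known composition used by the pollen filter tests.
fixture_archive <- function(n = 500, seed = 99, taxa = "Fagus") {
  set.seed(seed)
  counts <- sample(c(150L, 200L, 201L, 250L, 500L, 1500L), n, replace = TRUE)
  sigma <- sample(c(50, 200, 499, 500, 650), n, replace = TRUE)
  env <- sample(c("terrestrial", "lacustrine", "marine"), n, replace = TRUE,
                prob = c(0.5, 0.35, 0.15))
  focal <- rbinom(n, counts, 0.05)
  out <- data.frame(site_id = sprintf("s%02d", sample.int(40, n, TRUE)),
                    x = runif(n, 0, 10), y = runif(n, 0, 10),
                    sample_age_bp = runif(n, 500, 12000),
                    age_uncertainty_yr = sigma,
                    depositional_env = env,
                    count_Fagus = focal,
                    count_other = counts - focal,
                    total_count = counts)
  attr(out, "taxa") <- taxa
  class(out) <- c("pollen_archive", class(out))
  out
}
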
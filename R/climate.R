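#' Climate trajectory specification
#'
#' Describes a Holocene-like climate history: an abrupt warming of
#' `amplitude` degrees completed over `transition` model-years after
#' `changepoint`, followed by stability, sampled as 30-year slices every
#' `step` model-years. Times are model-years before present (BP), so larger
#' values are older; the oldest slice (`t_start`) sits fully in the cold
#' state and slices younger than `changepoint - transition` are fully warmed.
#'
#' @param t_start,t_end oldest and youngest slice times, model-years BP
#'   (`t_start > t_end`).
#' @param step slice spacing in model-years (> 0; 250 mirrors the cadence of
#'   coupled-GCM paleo slices).
#' @param amplitude warming amplitude, degrees C.
#' @param changepoint time BP at which warming begins.
#' @param transition duration of the warming ramp, model-years.
#' @param south_damping polar-amplification factor: the warming (and hence
#'   the glacial cooling) amplitude is scaled by
#'   `1 - south_damping * rowfrac`, so the southern edge experiences a
#'   fraction `1 - south_damping` of the full amplitude and the northern
#'   edge the full amplitude. Keeps southern refugia climatically viable in
#'   the cold state, as in deglacial Europe.
#' @param noise_sd interannual temperature noise sd, degrees C.
#' @param precip_noise_sd interannual seasonal precipitation noise sd, mm.
#' @param temp_gradient north-south temperature span across the grid,
#'   degrees C (row 1 is coldest).
#' @param precip_gradient relative east-west precipitation modulation
#'   (fraction, applied as +/- half across columns).
#' @param base_temp annual-mean temperature at the southern edge in the
#'   warm state, degrees C.
#' @param base_precip seasonal precipitation normals (length-4 vector, mm:
#'   winter, spring, summer, autumn).
#' @return an object of class `climate_trajectory`.
#' @export
climate_trajectory <- function(t_start = 12000, t_end = 500, step = 250,
                               amplitude = 8, changepoint = 11500,
                               transition = 500, south_damping = 0.5,
                               noise_sd = 0.8,
                               precip_noise_sd = 25,
                               temp_gradient = 8, precip_gradient = 0.3,
                               base_temp = 12,
                               base_precip = c(220, 180, 160, 210)) {
  if (step <= 0) stopf("slice spacing must be positive")
  if (t_end >= t_start) stopf("t_end must be before (younger than) t_start")
  if (length(base_precip) != 4L) stopf("base_precip must have 4 seasons")
  structure(as.list(environment()), class = "climate_trajectory")
}

# Warming offset (degrees C, <= 0) added to all temperatures at time t BP.
warming_offset <- function(trajectory, time_bp) {
  cp <- trajectory$changepoint
  tr <- trajectory$transition
  frac <- pmin(pmax((cp - time_bp) / tr, 0), 1)  # 0 before cp, 1 after ramp
  -trajectory$amplitude * (1 - frac)
}

# Season structure used throughout: 1 winter, 2 spring, 3 summer, 4 autumn.
SEASONS <- c("winter", "spring", "summer", "autumn")
SEASON_TEMP_OFFSET <- c(winter = -8, spring = 0, summer = 9, autumn = 1)

# Coldest-month minimum sits below the winter 3-month mean by a fixed offset.
COLD_MONTH_OFFSET <- 6
# Growing degree-days: spring + summer seasons, ~91 days each, base 5 C.
GDD_DAYS_PER_SEASON <- 91.25
# Early-summer water balance: two months of the summer season's precipitation
# minus a linear temperature-driven evapotranspiration demand.
WB_PRECIP_FRACTION <- 2 / 3
WB_PET_PER_DEGREE <- 9

# Derive 30-year-window covariates from per-year seasonal fields.
# temp, precip: arrays [n_rows, n_cols, 4 seasons, n_years].
derive_covariates <- function(temp, precip) {
  tw <- apply(temp[, , 1L, , drop = FALSE], c(1, 2), mean)
  ts <- temp[, , 2L, , drop = FALSE]
  tsu <- temp[, , 3L, , drop = FALSE]
  gdd_y <- pmax(ts - 5, 0) * GDD_DAYS_PER_SEASON +
    pmax(tsu - 5, 0) * GDD_DAYS_PER_SEASON
  gdd <- apply(gdd_y, c(1, 2), mean)
  precip_total <- apply(apply(precip, c(1, 2, 4), sum), c(1, 2), mean)
  wb_y <- WB_PRECIP_FRACTION * precip[, , 3L, , drop = FALSE] -
    WB_PET_PER_DEGREE * pmax(tsu, 0)
  wb <- apply(wb_y, c(1, 2), mean)
  list(tmin_winter = tw - COLD_MONTH_OFFSET, gdd = gdd,
       precip_total = precip_total, water_balance_summer = wb)
}

new_climate_slice <- function(time_bp, temp, precip) {
  cov <- derive_covariates(temp, precip)
  structure(c(list(time_bp = time_bp,
                   seasonal_temp = temp, seasonal_precip = precip),
              cov),
            class = "climate_slice")
}

#' @exportS3Method base::print
print.climate_slice <- function(x, ...) {
  cat(sprintf(
    "<climate_slice> t = %s BP, %d x %d cells, %d years; mean tmin_winter %.2f C\n",
    format(x$time_bp), nrow(x$tmin_winter), ncol(x$tmin_winter),
    dim(x$seasonal_temp)[4L], mean(x$tmin_winter)))
  invisible(x)
}

#' Generate a synthetic climate slice series
#'
#' Produces one `climate_slice` every `trajectory$step` model-years from
#' `t_start` down to `t_end`. Each slice carries per-cell, per-year seasonal
#' fields (four 3-month temperature means and four 3-month precipitation
#' sums for each of `n_years` years) plus the derived 30-year covariates
#' used by the suitability models: minimum temperature of the coldest month,
#' growing degree-days above 5 degrees, total annual precipitation, and
#' early-summer water balance.
#'
#' The deterministic part of the field is a north-south temperature gradient,
#' an east-west precipitation gradient and the trajectory's warming ramp;
#' interannual noise is iid Gaussian per cell, season and year. With
#' `noise_sd = 0` and `precip_noise_sd = 0` the output is an exact function
#' of (time, position); with a seed it is bit-reproducible.
#'
#' @param config a [landscape_config()].
#' @param trajectory a [climate_trajectory()].
#' @param n_years simulated years per 30-year window.
#' @param seed stage seed; defaults to one derived from `config$seed`.
#' @return a list of `climate_slice` objects, oldest first.
#' @export
gen_climate_series <- function(config, trajectory, n_years = 30,
                               seed = NULL) {
  stopifnot(inherits(config, "landscape_config"),
            inherits(trajectory, "climate_trajectory"))
  seed <- seed %||% derive_seed(config$seed, 1L)
  times <- seq(trajectory$t_start, trajectory$t_end, by = -trajectory$step)
  nr <- config$n_rows; nc <- config$n_cols
  rowfrac <- matrix((seq_len(nr) - 1) / (nr - 1), nr, nc)
  colfrac <- matrix((seq_len(nc) - 1) / (nc - 1), nr, nc, byrow = TRUE)
  t_mean0 <- trajectory$base_temp - trajectory$temp_gradient * (1 - rowfrac)
  p_mod <- 1 + trajectory$precip_gradient * (colfrac - 0.5)
  damp <- 1 - (trajectory$south_damping %||% 0) * rowfrac
  with_seed(seed, {
    lapply(times, function(tt) {
      off <- warming_offset(trajectory, tt) * damp
      temp <- array(0, c(nr, nc, 4L, n_years))
      precip <- array(0, c(nr, nc, 4L, n_years))
      for (s in 1:4) {
        mu_t <- t_mean0 + SEASON_TEMP_OFFSET[s] + off
        mu_p <- trajectory$base_precip[s] * p_mod
        for (y in seq_len(n_years)) {
          temp[, , s, y] <- mu_t +
            matrix(stats::rnorm(nr * nc, 0, trajectory$noise_sd), nr, nc)
          precip[, , s, y] <- pmax(
            mu_p + matrix(stats::rnorm(nr * nc, 0,
                                       trajectory$precip_noise_sd), nr, nc),
            0)
        }
      }
      new_climate_slice(tt, temp, precip)
    })
  })
}

#' Elevation-correct a coarse climate slice onto a nested fine grid
#'
#' Applies a constant lapse-rate correction: every fine-cell temperature is
#' the enclosing coarse cell's temperature minus
#' `lapse_rate * (fine_elev - coarse_elev) / 1000`. Precipitation is copied
#' unchanged. The correction is applied to the per-year seasonal temperature
#' fields, and the derived covariates (coldest-month minimum, degree-days,
#' water balance) are recomputed from the corrected fields, so the linear
#' shift propagates consistently.
#'
#' @param coarse a `climate_slice` on the coarse grid.
#' @param fine_elevation elevation matrix on the fine grid, metres; its
#'   dimensions must be an integer multiple of the coarse dimensions.
#' @param coarse_elevation coarse elevation matrix (defaults to 0, i.e. the
#'   fine elevations are anomalies).
#' @param lapse_rate degrees C per km (standard-atmosphere 6.5 by default).
#' @return a `climate_slice` on the fine grid.
#' @export
downscale_elevation <- function(coarse, fine_elevation,
                                coarse_elevation = NULL, lapse_rate = 6.5) {
  stopifnot(inherits(coarse, "climate_slice"))
  nr <- nrow(coarse$tmin_winter); nc <- ncol(coarse$tmin_winter)
  if (nrow(fine_elevation) %% nr != 0L || ncol(fine_elevation) %% nc != 0L ||
      nrow(fine_elevation) %/% nr != ncol(fine_elevation) %/% nc) {
    stopf("fine elevation grid does not nest in the coarse grid")
  }
  f <- nrow(fine_elevation) %/% nr
  if (is.null(coarse_elevation)) coarse_elevation <- matrix(0, nr, nc)
  delta <- fine_elevation - broadcast_to_fine(coarse_elevation, f)
  shift <- lapse_rate * delta / 1000
  dims <- dim(coarse$seasonal_temp)
  n_years <- dims[4L]
  temp <- array(0, c(nr * f, nc * f, 4L, n_years))
  precip <- array(0, c(nr * f, nc * f, 4L, n_years))
  for (s in 1:4) for (y in seq_len(n_years)) {
    temp[, , s, y] <- broadcast_to_fine(coarse$seasonal_temp[, , s, y], f) -
      shift
    precip[, , s, y] <- broadcast_to_fine(coarse$seasonal_precip[, , s, y], f)
  }
  new_climate_slice(coarse$time_bp, temp, precip)
}
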
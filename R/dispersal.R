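# Dispersal-limited cellular automaton: annual colonisation from occupied
# fine cells through a discretised short-distance kernel plus rare
# long-distance events, driven by suitability maps updated every slice.

#' Construct a dispersal kernel object
#'
#' Low-level constructor. `short_kernel` holds per-offset weights over a
#' square window of radius `radius` cells; [discretize_kernel()] produces
#' normalised (sum-to-one) landing distributions from continuous densities,
#' but the constructor also accepts unnormalised per-target colonisation
#' probabilities (`normalize = FALSE`), which is how deterministic test
#' kernels are built.
#'
#' @param short_kernel square (2 * radius + 1)^2 weight matrix, entries >= 0.
#' @param cell_size_m fine-cell edge length, metres.
#' @param ld_probability per-source per-year probability of one
#'   long-distance event.
#' @param ld_sampler function(n) returning long-distance dispersal distances
#'   in metres (beyond the short-kernel radius), or `NULL`.
#' @param normalize rescale `short_kernel` to sum to one.
#' @param form,params bookkeeping about the continuous density, if any.
#' @return an object of class `dispersal_kernel`.
#' @export
dispersal_kernel <- function(short_kernel, cell_size_m = 500,
                             ld_probability = 0.01, ld_sampler = NULL,
                             normalize = TRUE, form = "custom",
                             params = NULL) {
  short_kernel <- as.matrix(short_kernel)
  if (nrow(short_kernel) != ncol(short_kernel) ||
      nrow(short_kernel) %% 2L == 0L) {
    stopf("short_kernel must be a square odd-sized matrix")
  }
  if (any(short_kernel < 0)) stopf("kernel weights must be >= 0")
  if (ld_probability < 0 || ld_probability > 1) {
    stopf("ld_probability must be in [0, 1]")
  }
  if (normalize) short_kernel <- short_kernel / sum(short_kernel)
  structure(list(short_kernel = short_kernel,
                 radius = (nrow(short_kernel) - 1L) %/% 2L,
                 cell_size_m = cell_size_m,
                 ld_probability = ld_probability,
                 ld_sampler = ld_sampler, form = form, params = params),
            class = "dispersal_kernel")
}

#' @exportS3Method base::print
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf(
    "<dispersal_kernel> %s, radius %d cells (%g m), ld prob %g\n",
    x$form, x$radius, x$radius * x$cell_size_m, x$ld_probability))
  invisible(x)
}

# Unnormalised radial densities (2-D, per unit area).
kernel_density_fun <- function(form, params) {
  a <- params$a
  switch(form,
    exponential_power = {
      b <- params$b
      if (a <= 0 || b <= 0) stopf("exponential-power needs a > 0, b > 0")
      function(r) exp(-(r / a)^b)
    },
    twodt = {
      b <- params$b
      if (a <= 0 || b <= 1) stopf("2Dt kernel needs a > 0, b > 1 to be integrable")
      function(r) (1 + r^2 / a^2)^(-b)
    },
    stopf("unknown kernel form '%s'", form))
}

# Mass of the continuous kernel inside radius R (metres).
kernel_mass_within <- function(f, R, norm_const) {
  stats::integrate(function(r) 2 * pi * r * f(r), 0, R,
                   rel.tol = 1e-8)$value / norm_const
}

#' Discretise a fat-tailed dispersal kernel onto the fine grid
#'
#' Evaluates the continuous 2-D density at each cell-offset midpoint within
#' `radius` cells (midpoint rule over the offset cell), renormalises the
#' truncated matrix to sum to one, and builds an inverse-CDF sampler for the
#' tail beyond the radius, used for long-distance events. If `radius` is
#' `NULL` it is chosen as the smallest radius whose truncated mass reaches
#' `target_mass` (capped at `max_radius` cells, with a warning if the cap
#' binds — expected for very fat tails, whose far mass is then handled by
#' the long-distance pathway).
#'
#' @param form `"exponential_power"` (`exp(-(r/a)^b)`) or `"twodt"`
#'   (`(1 + r^2/a^2)^(-b)`, integrable for `b > 1`).
#' @param params list with `a` (metres) and `b` (shape).
#' @param radius short-kernel radius in cells, or `NULL` to auto-select.
#' @param cell_size fine-cell size, metres.
#' @param ld_probability per-source per-year long-distance probability.
#' @param target_mass continuous mass the short kernel should capture.
#' @param max_radius cap on the auto-selected radius, cells.
#' @return a [dispersal_kernel()].
#' @export
discretize_kernel <- function(form = c("exponential_power", "twodt"),
                              params, radius = NULL, cell_size = 500,
                              ld_probability = 0.01, target_mass = 0.99,
                              max_radius = 25L) {
  form <- match.arg(form)
  f <- kernel_density_fun(form, params)
  norm_const <- stats::integrate(function(r) 2 * pi * r * f(r), 0, Inf,
                                 rel.tol = 1e-8)$value
  if (!is.finite(norm_const) || norm_const <= 0) {
    stopf("kernel parameters do not give an integrable density")
  }
  if (is.null(radius)) {
    radius <- 1L
    while (radius < max_radius &&
           kernel_mass_within(f, (radius + 0.5) * cell_size,
                              norm_const) < target_mass) {
      radius <- radius + 1L
    }
    if (kernel_mass_within(f, (radius + 0.5) * cell_size,
                           norm_const) < target_mass) {
      warning(sprintf(
        "short kernel truncated at %d cells holds < %.0f%% of the mass; the tail is left to long-distance events",
        radius, 100 * target_mass))
    }
  }
  radius <- as.integer(radius)
  # integrate the density over each offset cell with a 5x5 subgrid of
  # midpoints; a single central midpoint overweights the origin cell for
  # sharply peaked densities
  sub <- (seq_len(5) - 3) / 5 * cell_size
  size <- 2L * radius + 1L
  mat <- matrix(0, size, size)
  off <- seq(-radius, radius) * cell_size
  for (sx in sub) for (sy in sub) {
    d <- sqrt(outer((off + sy)^2, (off + sx)^2, "+"))
    mat <- mat + f(d)
  }
  mat <- mat * cell_size^2 / 25
  mat <- mat / sum(mat)

  # Inverse-CDF sampler for distances beyond the short-kernel radius.
  r_lo <- (radius + 0.5) * cell_size
  tail_mass <- 1 - kernel_mass_within(f, r_lo, norm_const)
  ld_sampler <- NULL
  if (tail_mass > 1e-10) {
    r_hi <- r_lo * 2
    target <- 0.999 * tail_mass
    while (kernel_mass_within(f, r_hi, norm_const) - (1 - tail_mass) <
           target && r_hi < r_lo * 1e4) {
      r_hi <- r_hi * 2
    }
    grid <- seq(r_lo, r_hi, length.out = 512L)
    dens <- 2 * pi * grid * f(grid) / norm_const
    cdf <- cumsum(c(0, diff(grid) * (dens[-1] + dens[-length(dens)]) / 2))
    cdf <- cdf / cdf[length(cdf)]
    ok <- !duplicated(cdf)
    ld_sampler <- local({
      g <- grid[ok]; cc <- cdf[ok]
      function(n) stats::approx(cc, g, xout = stats::runif(n),
                                rule = 2)$y
    })
  }
  dispersal_kernel(mat, cell_size_m = cell_size,
                   ld_probability = ld_probability, ld_sampler = ld_sampler,
                   normalize = FALSE, form = form, params = params)
}

#' Threshold and rescale a suitability map into colonisation probabilities
#'
#' Cells at or below the species' threshold get probability zero (the
#' species cannot survive there); above the threshold, suitability is
#' rescaled linearly to `[0, 1]` as `(v - tau) / (v_max - tau)`, where
#' `v_max` is the species/model maximum over the calibration-period domain,
#' frozen so maps are comparable across slices. The result is interpreted as
#' the probability that a propagule-reached cell becomes colonised.
#'
#' @param map a `suitability_map`.
#' @param tau threshold (defaults to `map$threshold`).
#' @param v_max frozen rescaling maximum (defaults to `map$v_max`).
#' @return a `suitability_map` with `rescaled = TRUE`; values in `[0, 1]`.
#' @export
threshold_rescale <- function(map, tau = map$threshold, v_max = map$v_max) {
  stopifnot(inherits(map, "suitability_map"))
  if (is.na(tau)) stopf("no threshold set on this map")
  if (is.na(v_max)) v_max <- max(map$values)
  if (v_max <= tau) {
    stopf("no suitable cell anywhere: v_max (%.4f) <= tau (%.4f)",
          v_max, tau, class = "paleoshift_empty_map")
  }
  v <- map$values
  out <- pmin(pmax((v - tau) / (v_max - tau), 0), 1)
  out[v <= tau] <- 0
  new_suitability_map(out, map$species, map$time_bp, threshold = tau,
                      v_max = v_max, rescaled = TRUE)
}

new_occupancy_grid <- function(occupied, time_bp) {
  structure(list(occupied = occupied, time_bp = time_bp),
            class = "occupancy_grid")
}

#' @exportS3Method base::print
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> t = %s BP, %d x %d fine cells, %d occupied\n",
              format(x$time_bp), nrow(x$occupied), ncol(x$occupied),
              sum(x$occupied)))
  invisible(x)
}

#' Initialise occupancy from the first slice with suitable cells
#'
#' All fine cells of coarse cells with positive colonisation probability in
#' the starting slice are occupied (the model's initial starting points).
#' If the first map is empty the start is deferred slice by slice, up to
#' `max_defer` deferrals; if no slice within reach has a suitable cell an
#' error is raised.
#'
#' @param prob_maps list of rescaled `suitability_map`s, oldest first.
#' @param config a [landscape_config()].
#' @param max_defer how many slices the start may be deferred.
#' @return a list with `occ` (an `occupancy_grid`) and `start_index`.
#' @export
init_occupancy <- function(prob_maps, config, max_defer = 3L) {
  last <- min(length(prob_maps), 1L + max_defer)
  for (i in seq_len(last)) {
    p <- prob_maps[[i]]$values
    if (any(p > 0)) {
      occ <- broadcast_to_fine(p > 0, config$fine_per_coarse)
      return(list(occ = new_occupancy_grid(occ, prob_maps[[i]]$time_bp),
                  start_index = i))
    }
  }
  stopf("no suitable cell in the first %d slices", last,
        class = "paleoshift_empty_map")
}

# Arrival-probability clamp: FFT leakage below this is treated as exact 0,
# and values this close to 1 as exact 1 (keeps deterministic kernels exact).
ARRIVAL_EPS <- 1e-9

#' One annual dispersal step
#'
#' Synchronous update from the current occupancy: an unoccupied cell with
#' colonisation probability `p` becomes occupied with probability
#' `p * (1 - prod over occupied sources of (1 - k(source -> cell)))` within
#' short-kernel reach (propagule arrival times establishment); independently
#' each occupied source triggers, with probability `ld_probability`, one
#' long-distance propagule at a sampled distance and uniform angle, which
#' colonises its landing cell with probability equal to that cell's `p`
#' (off-grid landings are lost). Occupied cells stay occupied; cells with
#' `p = 0` never colonise. Consumes the current RNG stream.
#'
#' @param occ an `occupancy_grid` on the fine grid.
#' @param prob_fine colonisation-probability matrix on the fine grid.
#' @param kernel a [dispersal_kernel()].
#' @param kern_fft optional precomputed kernel FFT (internal fast path).
#' @return the updated `occupancy_grid`.
#' @export
disperse_step <- function(occ, prob_fine, kernel, kern_fft = NULL) {
  stopifnot(inherits(occ, "occupancy_grid"))
  O <- occ$occupied
  if (!all(dim(O) == dim(prob_fine))) stopf("misaligned occupancy/probability grids")
  newly <- integer(0)

  cand <- which(!O & prob_fine > 0)
  if (length(cand) && any(O)) {
    k <- pmin(kernel$short_kernel, 1 - 1e-15)
    logk <- matrix(log1p(-k), nrow(k), ncol(k))
    pad <- conv2d_pad(dim(O), kernel$radius)
    if (is.null(kern_fft)) kern_fft <- conv2d_kernel_fft(logk, pad)
    S <- conv2d_same(O + 0, logk, k_fft = kern_fft, pad = pad)
    A <- 1 - exp(S[cand])
    A[A < ARRIVAL_EPS] <- 0
    A[A > 1 - ARRIVAL_EPS] <- 1
    u <- stats::runif(length(cand))
    newly <- cand[u < prob_fine[cand] * A]
  }

  if (kernel$ld_probability > 0 && !is.null(kernel$ld_sampler) && any(O)) {
    src <- which(O)
    trig <- src[stats::runif(length(src)) < kernel$ld_probability]
    if (length(trig)) {
      d <- kernel$ld_sampler(length(trig))
      theta <- stats::runif(length(trig), 0, 2 * pi)
      nr <- nrow(O)
      sr <- ((trig - 1L) %% nr) + 1L
      sc <- ((trig - 1L) %/% nr) + 1L
      tr <- sr + round(d * sin(theta) / kernel$cell_size_m)
      tc <- sc + round(d * cos(theta) / kernel$cell_size_m)
      ok <- tr >= 1 & tr <= nr & tc >= 1 & tc <= ncol(O)
      if (any(ok)) {
        land <- cbind(tr[ok], tc[ok])
        p_land <- prob_fine[land]
        est <- stats::runif(nrow(land)) < p_land
        if (any(est)) {
          li <- (land[est, 2L, drop = TRUE] - 1L) * nr +
            land[est, 1L, drop = TRUE]
          newly <- c(newly, li[!O[li]])
        }
      }
    }
  }

  if (length(newly)) O[newly] <- TRUE
  new_occupancy_grid(O, occ$time_bp)
}

#' Run the migration cellular automaton over a suitability series
#'
#' Initialises occupancy with [init_occupancy()], then, for each slice,
#' broadcasts the slice's colonisation-probability map to the fine grid,
#' vacates occupied cells whose probability dropped to zero (local
#' extinction where the species cannot survive), and performs
#' `years_per_slice` annual [disperse_step()]s. One occupancy snapshot is
#' recorded per slice, representing the state after migrating through that
#' slice's years. Within a slice, once every positive-probability cell is
#' occupied (or occupancy is empty) the state is absorbing until the next
#' suitability update and the remaining years are skipped.
#'
#' @param prob_series list of rescaled `suitability_map`s, oldest first.
#' @param kernel a [dispersal_kernel()].
#' @param config a [landscape_config()].
#' @param years_per_slice annual steps between suitability updates.
#' @param max_defer passed to [init_occupancy()].
#' @param seed stage seed.
#' @return a list with `occupancy` (list of `occupancy_grid`, one per slice;
#'   slices before the deferred start are all-empty grids) and `start_index`.
#' @export
run_migration <- function(prob_series, kernel, config,
                          years_per_slice = 250, max_defer = 3L,
                          seed = NULL) {
  if (!length(prob_series)) stopf("empty suitability series")
  init <- init_occupancy(prob_series, config, max_defer = max_defer)
  f <- config$fine_per_coarse
  dims <- fine_dim(config)
  pad <- conv2d_pad(dims, kernel$radius)
  logk <- matrix(log1p(-pmin(kernel$short_kernel, 1 - 1e-15)),
                 nrow(kernel$short_kernel), ncol(kernel$short_kernel))
  kern_fft <- conv2d_kernel_fft(logk, pad)

  occ <- init$occ
  snapshots <- vector("list", length(prob_series))
  empty <- new_occupancy_grid(matrix(FALSE, dims[1L], dims[2L]), NA_real_)
  with_seed(seed, {
    for (i in seq_along(prob_series)) {
      tt <- prob_series[[i]]$time_bp
      if (i < init$start_index) {
        snapshots[[i]] <- new_occupancy_grid(empty$occupied, tt)
        next
      }
      p_fine <- broadcast_to_fine(prob_series[[i]]$values, f)
      O <- occ$occupied
      O[p_fine == 0] <- FALSE     # vacate newly unsuitable cells
      occ <- new_occupancy_grid(O, tt)
      for (yr in seq_len(years_per_slice)) {
        if (!any(occ$occupied)) break
        if (!any(!occ$occupied & p_fine > 0)) break  # absorbing until update
        occ <- disperse_step(occ, p_fine, kernel, kern_fft = kern_fft)
      }
      occ$time_bp <- tt
      snapshots[[i]] <- occ
    }
  })
  list(occupancy = snapshots, start_index = init$start_index)
}

#' Combine two deciduous suitability maps
#'
#' Elementwise maximum, used to treat two interfertile deciduous species as
#' one pollen-equivalent taxon.
#'
#' @param mapA,mapB `suitability_map`s on the same grid and time.
#' @return a `suitability_map`.
#' @export
combine_deciduous <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "suitability_map"),
            inherits(mapB, "suitability_map"))
  if (!all(dim(mapA$values) == dim(mapB$values))) stopf("shape mismatch")
  if (!identical(mapA$time_bp, mapB$time_bp)) stopf("time mismatch")
  new_suitability_map(pmax(mapA$values, mapB$values),
                      paste(mapA$species, mapB$species, sep = "+"),
                      mapA$time_bp,
                      threshold = mapA$threshold, v_max = mapA$v_max,
                      rescaled = mapA$rescaled && mapB$rescaled)
}

#' Aggregate fine occupancy to coarse presence
#'
#' A coarse cell is present iff at least one of its fine cells is occupied.
#'
#' @param occ an `occupancy_grid` (or logical fine matrix).
#' @param f integer nesting factor.
#' @return a logical coarse matrix.
#' @export
coarsen_occupancy <- function(occ, f) {
  m <- if (inherits(occ, "occupancy_grid")) occ$occupied else occ
  block_counts(m, f) > 0
}
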
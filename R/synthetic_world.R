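# Ground-truth occupancy and virtual fossil-pollen archives: the inputs the
# real study draws from paleoclimate simulators and pollen databases, here
# generated with known truth so every downstream stage is testable.

#' Generate the true occupancy series of a virtual species
#'
#' The ground truth combines the species' mechanistic fitness
#' ([process_fitness()]) with the migration automaton ([run_migration()]):
#' fitness below `tau` is uninhabitable, fitness above is rescaled against a
#' frozen maximum (the series-wide fitness maximum) and used as colonisation
#' probability.
#'
#' @param species a [virtual_species()].
#' @param slices list of `climate_slice`s, oldest first.
#' @param kernel a [dispersal_kernel()].
#' @param config a [landscape_config()].
#' @param tau truth habitability threshold on fitness.
#' @param years_per_slice annual steps per slice.
#' @param seed stage seed.
#' @return a list with `occupancy` (fine `occupancy_grid` per slice),
#'   `presence` (coarse logical matrix per slice), `suitability`,
#'   `prob_series`, `start_index`.
#' @export
gen_true_occupancy <- function(species, slices, kernel, config, tau = 0.1,
                               years_per_slice = 250, seed = NULL) {
  suit <- lapply(slices, process_fitness, species = species)
  v_max <- max(vapply(suit, function(m) max(m$values), numeric(1)))
  prob <- lapply(suit, threshold_rescale, tau = tau, v_max = v_max)
  mig <- run_migration(prob, kernel, config,
                       years_per_slice = years_per_slice, seed = seed)
  presence <- lapply(mig$occupancy, coarsen_occupancy,
                     f = config$fine_per_coarse)
  list(occupancy = mig$occupancy, presence = presence, suitability = suit,
       prob_series = prob, start_index = mig$start_index)
}

#' Default pollen archive plan
#'
#' Site placement, sampling cadence, grain-count and age-uncertainty
#' distributions, and the detection model. Counts are lognormal around ~320
#' grains (a realistic share of samples falls below a 200-grain filter) and
#' age uncertainties lognormal around ~150 years (a small share exceeds a
#' 500-year filter), so downstream filtering rules are exercised by
#' construction.
#'
#' @param n_sites number of pollen sites.
#' @param marine_fraction fraction of sites with a marine depositional
#'   environment.
#' @param p_sample probability that a site yields a sample at a slice time.
#' @param count_meanlog,count_sdlog lognormal parameters of total grain
#'   counts.
#' @param age_meanlog,age_sdlog lognormal parameters of age uncertainty
#'   (years).
#' @param detection expected relative abundance of a focal taxon when its
#'   cell is occupied / unoccupied.
#' @return a list, passed to [gen_pollen_archive()].
#' @export
pollen_plan <- function(n_sites = 150, marine_fraction = 0.1,
                        p_sample = 0.8,
                        count_meanlog = log(320), count_sdlog = 0.5,
                        age_meanlog = log(150), age_sdlog = 0.7,
                        detection = list(occupied = 0.08,
                                         unoccupied = 0.002)) {
  as.list(environment())
}

#' Generate a virtual fossil-pollen archive
#'
#' Sites are placed uniformly on the coarse grid; a configurable fraction is
#' tagged marine. Each site yields, with probability `plan$p_sample` per
#' slice, one sample whose true age is uniform within the slice interval,
#' whose reported age is the true age jittered by its (lognormal) age
#' uncertainty, and whose grain counts are multinomial: each focal taxon's
#' expected relative abundance is `detection$occupied` where the taxon truly
#' occupies the site's coarse cell at the sample's true age and
#' `detection$unoccupied` elsewhere, the remainder going to an "other"
#' pollen pool.
#'
#' @param truth named list (one element per taxon) of coarse presence series
#'   as returned in `gen_true_occupancy()$presence`.
#' @param times numeric vector of slice times BP matching the series.
#' @param config a [landscape_config()].
#' @param plan a [pollen_plan()].
#' @param seed stage seed.
#' @return a data.frame of class `pollen_archive` with columns `site_id`,
#'   `x`, `y`, `sample_age_bp`, `age_uncertainty_yr`, `depositional_env`,
#'   one `count_<taxon>` column per taxon plus `count_other`, and
#'   `total_count`; the taxa are recorded in attribute `taxa`.
#' @export
gen_pollen_archive <- function(truth, times, config, plan = pollen_plan(),
                               seed = NULL) {
  taxa <- names(truth)
  if (is.null(taxa) || !length(taxa)) stopf("truth must be a named list of presence series")
  det <- plan$detection
  if (any(unlist(det) < 0) || any(unlist(det) > 1)) {
    stopf("detection probabilities must be in [0, 1]")
  }
  if (length(taxa) * det$occupied >= 1) {
    stopf("detection$occupied too large for %d taxa", length(taxa))
  }
  step <- if (length(times) > 1) abs(diff(times[1:2])) else 250
  seed <- seed %||% derive_seed(config$seed, 3L)
  with_seed(seed, {
    n <- plan$n_sites
    sx <- stats::runif(n, 0, config$n_cols)
    sy <- stats::runif(n, 0, config$n_rows)
    env <- ifelse(stats::runif(n) < plan$marine_fraction, "marine",
                  ifelse(stats::runif(n) < 0.5, "lacustrine", "terrestrial"))
    rows <- list()
    for (s in seq_len(n)) {
      cell_r <- min(floor(sy[s]) + 1L, config$n_rows)
      cell_c <- min(floor(sx[s]) + 1L, config$n_cols)
      for (ti in seq_along(times)) {
        if (stats::runif(1) >= plan$p_sample) next
        true_age <- times[ti] + stats::runif(1, -step / 2, step / 2)
        sigma <- stats::rlnorm(1, plan$age_meanlog, plan$age_sdlog)
        rep_age <- true_age + stats::rnorm(1, 0, sigma)
        total <- max(1L, round(stats::rlnorm(1, plan$count_meanlog,
                                             plan$count_sdlog)))
        p_taxa <- vapply(taxa, function(tx) {
          if (truth[[tx]][[ti]][cell_r, cell_c]) det$occupied
          else det$unoccupied
        }, numeric(1))
        counts <- as.integer(stats::rmultinom(
          1, total, c(p_taxa, 1 - sum(p_taxa))))
        rows[[length(rows) + 1L]] <- c(
          list(site_id = sprintf("site_%03d", s), x = sx[s], y = sy[s],
               sample_age_bp = rep_age, age_uncertainty_yr = sigma,
               depositional_env = env[s]),
          stats::setNames(as.list(counts[seq_along(taxa)]),
                          paste0("count_", taxa)),
          list(count_other = counts[length(counts)],
               total_count = total))
      }
    }
    out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    attr(out, "taxa") <- taxa
    class(out) <- c("pollen_archive", class(out))
    out
  })
}
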
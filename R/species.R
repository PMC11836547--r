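#' Define a virtual species
#'
#' A mechanistic species described by three logistic response curves whose
#' product is its fitness: winter frost survival (rising in the coldest-month
#' minimum temperature), summer drought survival (rising in early-summer
#' water balance) and reproductive success (rising in growing degree-days).
#' Each curve is `plogis((x - midpoint) / slope)`, so the midpoint is the
#' value at which the component equals 0.5 and the slope (same units as the
#' covariate) sets how sharp the limit is.
#'
#' @param name species label.
#' @param frost_t50,frost_slope frost-survival midpoint and scale, degrees C.
#' @param drought_w50,drought_slope drought-survival midpoint and scale, mm.
#' @param gdd_req,gdd_slope reproduction midpoint and scale, degree-days.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(name, frost_t50 = -15, frost_slope = 2,
                            drought_w50 = -120, drought_slope = 20,
                            gdd_req = 900, gdd_slope = 150) {
  if (frost_slope <= 0 || drought_slope <= 0 || gdd_slope <= 0) {
    stopf("all slope parameters must be positive")
  }
  structure(list(name = name,
                 frost_t50 = frost_t50, frost_slope = frost_slope,
                 drought_w50 = drought_w50, drought_slope = drought_slope,
                 gdd_req = gdd_req, gdd_slope = gdd_slope),
            class = "virtual_species")
}

#' @exportS3Method base::print
print.virtual_species <- function(x, ...) {
  cat(sprintf(
    "<virtual_species> %s: frost %.1f C (s %.1f), drought %.0f mm (s %.0f), gdd %.0f (s %.0f)\n",
    x$name, x$frost_t50, x$frost_slope, x$drought_w50, x$drought_slope,
    x$gdd_req, x$gdd_slope))
  invisible(x)
}

species_params <- function(species) {
  unlist(species[c("frost_t50", "frost_slope", "drought_w50",
                   "drought_slope", "gdd_req", "gdd_slope")])
}

species_from_params <- function(par, name) {
  virtual_species(name,
                  frost_t50 = par[["frost_t50"]],
                  frost_slope = par[["frost_slope"]],
                  drought_w50 = par[["drought_w50"]],
                  drought_slope = par[["drought_slope"]],
                  gdd_req = par[["gdd_req"]],
                  gdd_slope = par[["gdd_slope"]])
}

new_suitability_map <- function(values, species, time_bp,
                                threshold = NA_real_, v_max = NA_real_,
                                rescaled = FALSE) {
  structure(list(values = values, species = species, time_bp = time_bp,
                 threshold = threshold, v_max = v_max, rescaled = rescaled),
            class = "suitability_map")
}

#' @exportS3Method base::print
print.suitability_map <- function(x, ...) {
  cat(sprintf(
    "<suitability_map> %s @ %s BP, %d x %d, range [%.3f, %.3f]%s\n",
    x$species, format(x$time_bp), nrow(x$values), ncol(x$values),
    min(x$values), max(x$values),
    if (isTRUE(x$rescaled)) " (colonisation probability)" else ""))
  invisible(x)
}

#' Mechanistic fitness of a virtual species under a climate slice
#'
#' Per-cell fitness is the product of the three logistic components of the
#' species evaluated on the slice covariates (coldest-month minimum
#' temperature, early-summer water balance, growing degree-days). Values lie
#' in (0, 1) and rise monotonically in each covariate.
#'
#' @param slice a `climate_slice`.
#' @param species a [virtual_species()].
#' @return a `suitability_map` of fitness values.
#' @export
process_fitness <- function(slice, species) {
  stopifnot(inherits(species, "virtual_species"))
  for (v in c("tmin_winter", "water_balance_summer", "gdd")) {
    if (is.null(slice[[v]])) stopf("slice is missing covariate '%s'", v)
  }
  vals <- fitness_from_covariates(slice$tmin_winter,
                                  slice$water_balance_summer,
                                  slice$gdd, species)
  new_suitability_map(vals, species$name, slice$time_bp)
}

fitness_from_covariates <- function(tmin, wb, gdd, species) {
  stats::plogis((tmin - species$frost_t50) / species$frost_slope) *
    stats::plogis((wb - species$drought_w50) / species$drought_slope) *
    stats::plogis((gdd - species$gdd_req) / species$gdd_slope)
}
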
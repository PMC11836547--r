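# Fossil-pollen processing: sample filters, 500-year binning with weighted
# averaging, abundance thresholding, range-based assignment of undetermined
# oak pollen, and aggregation to the coarse evaluation grid.

POLLEN_REQUIRED_COLS <- c("site_id", "x", "y", "sample_age_bp",
                          "age_uncertainty_yr", "depositional_env",
                          "total_count")

#' Filter pollen samples
#'
#' Retains samples with more than 200 pollen grains, age uncertainty below
#' 500 years, and a non-marine depositional environment (all three strict:
#' a sample with exactly 200 grains or exactly 500 years of uncertainty is
#' removed). The filters are conjunctive, hence order-independent.
#'
#' @param archive a `pollen_archive` data.frame.
#' @param min_count,max_age_uncertainty filter boundaries.
#' @return the retained rows, with attribute `removals` counting, for each
#'   criterion, how many samples failed it.
#' @export
filter_samples <- function(archive, min_count = 200,
                           max_age_uncertainty = 500) {
  miss <- setdiff(POLLEN_REQUIRED_COLS, names(archive))
  if (length(miss)) stopf("archive is missing column(s): %s",
                          paste(miss, collapse = ", "))
  low_count <- !(archive$total_count > min_count)
  high_age <- !(archive$age_uncertainty_yr < max_age_uncertainty)
  marine <- archive$depositional_env == "marine"
  keep <- !(low_count | high_age | marine)
  out <- archive[keep, , drop = FALSE]
  attr(out, "taxa") <- attr(archive, "taxa")
  attr(out, "removals") <- c(low_count = sum(low_count),
                             age_uncertainty = sum(high_age),
                             marine = sum(marine),
                             total_removed = sum(!keep))
  class(out) <- class(archive)
  out
}

bin_centre <- function(age, bin_width) {
  floor(age / bin_width) * bin_width + bin_width / 2
}

#' Bin pollen samples and average abundances within site and bin
#'
#' Samples are assigned to consecutive `bin_width`-year intervals (centres
#' at `bin_width/2 + k * bin_width` model-years BP, aligned with the slice
#' timeline). Within each site and bin, per-taxon relative abundances
#' (count / total grains) are averaged with weights
#' `w = 1/(sigma + 1) * max(0, 1 - |t - t_c| / (bin_width/2))`: inverse age
#' uncertainty times a triangular weight in the distance from the bin
#' centre. If every weight in a non-empty bin is zero (samples exactly on
#' the bin edges), the unweighted mean is used and the row is flagged.
#'
#' @param archive a (filtered) `pollen_archive`.
#' @param bin_width interval width, model-years (500 by default).
#' @param taxa taxa to tabulate (default: attribute of the archive).
#' @return a data.frame with columns `site_id`, `x`, `y`, `bin_centre_bp`,
#'   `taxon`, `relative_abundance`, `effective_weight`, `n_samples`,
#'   `fallback_unweighted`.
#' @export
bin_and_average <- function(archive, bin_width = 500,
                            taxa = attr(archive, "taxa")) {
  if (is.null(taxa)) stopf("no taxa given and none recorded on the archive")
  if (!nrow(archive)) {
    return(data.frame(site_id = character(), x = numeric(), y = numeric(),
                      bin_centre_bp = numeric(), taxon = character(),
                      relative_abundance = numeric(),
                      effective_weight = numeric(), n_samples = integer(),
                      fallback_unweighted = logical()))
  }
  bc <- bin_centre(archive$sample_age_bp, bin_width)
  key <- interaction(archive$site_id, bc, drop = TRUE)
  out <- lapply(split(seq_len(nrow(archive)), key), function(idx) {
    sub <- archive[idx, , drop = FALSE]
    tc <- bin_centre(sub$sample_age_bp[1L], bin_width)
    w <- 1 / (sub$age_uncertainty_yr + 1) *
      pmax(0, 1 - abs(sub$sample_age_bp - tc) / (bin_width / 2))
    fallback <- sum(w) == 0
    if (fallback) w <- rep(1, length(w))
    ab <- vapply(taxa, function(tx) {
      a <- sub[[paste0("count_", tx)]] / sub$total_count
      sum(w * a) / sum(w)
    }, numeric(1))
    data.frame(site_id = sub$site_id[1L], x = sub$x[1L], y = sub$y[1L],
               bin_centre_bp = tc, taxon = taxa,
               relative_abundance = unname(ab),
               effective_weight = sum(w), n_samples = nrow(sub),
               fallback_unweighted = fallback, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default pollen presence thresholds
#'
#' Relative-abundance thresholds above which a taxon is scored present,
#' following biome-reconstruction practice: 1% for beech and fir pollen,
#' 2.5% for oak pollen (oaks are prolific pollen producers).
#'
#' @return a named numeric vector of thresholds on `[0, 1]`.
#' @export
default_pollen_thresholds <- function() {
  c(Fagus = 0.01, Abies = 0.01, Quercus = 0.025,
    Quercus_deciduous = 0.025, Quercus_evergreen = 0.025)
}

#' Convert binned relative abundance to presence/absence
#'
#' Present iff `relative_abundance >= threshold[taxon]` (the comparison is
#' inclusive at the threshold).
#'
#' @param abundance numeric relative abundances in `[0, 1]`.
#' @param taxon character vector (recycled) naming each abundance's taxon.
#' @param thresholds named thresholds ([default_pollen_thresholds()]).
#' @return logical vector.
#' @export
abundance_to_presence <- function(abundance, taxon,
                                  thresholds = default_pollen_thresholds()) {
  taxon <- rep_len(as.character(taxon), length(abundance))
  unknown <- setdiff(unique(taxon), names(thresholds))
  if (length(unknown)) stopf("no presence threshold configured for taxon: %s",
                             paste(unknown, collapse = ", "))
  abundance >= unname(thresholds[taxon])
}

# Ray-casting point-in-polygon with an inclusive boundary. poly is a matrix
# of vertices (x, y), closed or open.
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L || ncol(poly) != 2L) stopf("invalid polygon geometry")
  if (all(poly[1L, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L) stopf("invalid polygon geometry")
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  eps <- 1e-12
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    # boundary: point on any edge counts as inside
    dx <- xe - xs; dy <- ye - ys
    cross <- dx * (y - ys) - dy * (x - xs)
    on_line <- abs(cross) <= eps * pmax(1, abs(dx) + abs(dy))
    within <- x >= pmin(xs, xe) - eps & x <= pmax(xs, xe) + eps &
      y >= pmin(ys, ye) - eps & y <= pmax(ys, ye) + eps
    if (any(on_line & within)) return(TRUE)
    crossing <- (ys > y) != (ye > y)
    if (!any(crossing)) return(FALSE)
    xint <- xs[crossing] + (y - ys[crossing]) / (ye[crossing] - ys[crossing]) *
      (xe[crossing] - xs[crossing])
    sum(xint > x) %% 2 == 1
  }, logical(1))
}

#' Assign undetermined oak pollen to deciduous-only or both categories
#'
#' Oak pollen that cannot be determined below the genus is assigned by the
#' site's position relative to the evergreen-oak natural range: sites
#' outside the range polygon count as deciduous-only occurrences, sites
#' inside (boundary inclusive) as both evergreen and deciduous occurrences.
#'
#' @param x,y site coordinates.
#' @param evergreen_range polygon vertex matrix (columns x, y).
#' @return character vector, `"deciduous-only"` or `"both"`.
#' @export
assign_undetermined_quercus <- function(x, y, evergreen_range) {
  inside <- point_in_polygon(x, y, evergreen_range)
  ifelse(inside, "both", "deciduous-only")
}

#' Aggregate site presences to the coarse grid
#'
#' A coarse cell is `present` for a taxon and bin if at least one of its
#' sites is present, `absent` if it has sites and all are absent; cells
#' without any retained site carry no state (no-data) and are simply not
#' listed — downstream evaluation is restricted to listed cells. Sites
#' falling outside the grid are skipped and logged.
#'
#' @param site_presence data.frame with columns `x`, `y`, `bin_centre_bp`,
#'   `taxon`, `present` (logical), e.g. [bin_and_average()] output plus a
#'   `present` column from [abundance_to_presence()].
#' @param config a [landscape_config()] (or list with `n_rows`, `n_cols`).
#' @return a data.frame of class `presence_grid` with columns `row`, `col`,
#'   `bin_centre_bp`, `taxon`, `state` (`"present"`/`"absent"`), `n_sites`;
#'   attribute `n_skipped` counts out-of-grid sites.
#' @export
grid_presence <- function(site_presence, config) {
  stopifnot(is.logical(site_presence$present))
  row <- floor(site_presence$y) + 1L
  col <- floor(site_presence$x) + 1L
  # sites exactly on the far edge belong to the last cell
  row[site_presence$y == config$n_rows] <- config$n_rows
  col[site_presence$x == config$n_cols] <- config$n_cols
  ok <- row >= 1L & row <= config$n_rows & col >= 1L & col <= config$n_cols
  n_skipped <- sum(!ok)
  sp <- site_presence[ok, , drop = FALSE]
  row <- row[ok]; col <- col[ok]
  key <- paste(row, col, sp$bin_centre_bp, sp$taxon, sep = "\r")
  agg <- lapply(split(seq_len(nrow(sp)), key), function(idx) {
    data.frame(row = row[idx[1L]], col = col[idx[1L]],
               bin_centre_bp = sp$bin_centre_bp[idx[1L]],
               taxon = sp$taxon[idx[1L]],
               state = if (any(sp$present[idx])) "present" else "absent",
               n_sites = length(idx))
  })
  out <- do.call(rbind, agg)
  if (is.null(out)) {
    out <- data.frame(row = integer(), col = integer(),
                      bin_centre_bp = numeric(), taxon = character(),
                      state = character(), n_sites = integer())
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "dims") <- c(config$n_rows, config$n_cols)
  class(out) <- c("presence_grid", class(out))
  out
}
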
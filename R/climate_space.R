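# Climatic dissimilarity between periods: seasonal feature tables, delta /
# ratio bias correction, reference PCA, bootstrapped Gaussian-KDE
# hypervolumes, Sørensen overlap, and Mahalanobis novelty.

SEASON_FEATURES <- c(paste0("T_", SEASONS), paste0("P_", SEASONS))

#' Seasonal climate feature table of a slice
#'
#' One row per cell and simulated year, with the four 3-month temperature
#' means (degrees C) and four 3-month precipitation sums (mm) — the feature
#' space in which climatic hypervolumes are built.
#'
#' @param slice a `climate_slice`.
#' @return a data.frame with columns `cell`, `year`, `T_winter`, ...,
#'   `P_autumn`.
#' @export
seasonal_features <- function(slice) {
  stopifnot(inherits(slice, "climate_slice"))
  dims <- dim(slice$seasonal_temp)
  if (length(dims) != 4L || dims[3L] != 4L) stopf("slice is missing a season")
  ncell <- dims[1L] * dims[2L]
  n_years <- dims[4L]
  tm <- matrix(aperm(slice$seasonal_temp, c(1, 2, 4, 3)), ncell * n_years, 4L)
  pm <- matrix(aperm(slice$seasonal_precip, c(1, 2, 4, 3)), ncell * n_years, 4L)
  out <- data.frame(cell = rep(seq_len(ncell), times = n_years),
                    year = rep(seq_len(n_years), each = ncell),
                    tm, pm)
  names(out)[-(1:2)] <- SEASON_FEATURES
  out
}

feature_matrix <- function(tab) {
  as.matrix(tab[, intersect(SEASON_FEATURES, names(tab)), drop = FALSE])
}

#' Delta / ratio bias correction of a simulated series
#'
#' Corrects a simulated slice series against observations over a common
#' reference window, assuming a constant bias: per cell and season, the
#' difference between observed and simulated mean temperature is added to
#' all simulated temperatures, and the ratio of observed to simulated mean
#' precipitation multiplies all simulated precipitation. Where the simulated
#' reference precipitation is below 1 mm the ratio is capped to `[0.2, 5]`
#' to avoid blow-ups in arid cells (flagged in attribute `n_capped`).
#' Derived covariates are recomputed from the corrected fields.
#'
#' @param sim_series list of simulated `climate_slice`s.
#' @param sim_reference,obs_reference `climate_slice`s for the common
#'   reference window.
#' @return the corrected list of `climate_slice`s.
#' @export
bias_correct <- function(sim_series, sim_reference, obs_reference) {
  dims <- dim(sim_reference$seasonal_temp)
  if (!all(dim(obs_reference$seasonal_temp)[1:3] == dims[1:3])) {
    stopf("reference windows do not overlap in cells and seasons")
  }
  t_sim <- apply(sim_reference$seasonal_temp, c(1, 2, 3), mean)
  t_obs <- apply(obs_reference$seasonal_temp, c(1, 2, 3), mean)
  p_sim <- apply(sim_reference$seasonal_precip, c(1, 2, 3), mean)
  p_obs <- apply(obs_reference$seasonal_precip, c(1, 2, 3), mean)
  delta <- t_obs - t_sim
  ratio <- p_obs / p_sim
  small <- p_sim < 1
  ratio[small] <- pmin(pmax(ratio[small], 0.2), 5)
  ratio[!is.finite(ratio)] <- 1
  n_capped <- sum(small)
  out <- lapply(sim_series, function(sl) {
    n_years <- dim(sl$seasonal_temp)[4L]
    temp <- sl$seasonal_temp + array(delta, dim(sl$seasonal_temp))
    precip <- sl$seasonal_precip * array(ratio, dim(sl$seasonal_precip))
    # array() recycles over years because the year dimension is last
    stopifnot(dim(temp)[4L] == n_years)
    new_climate_slice(sl$time_bp, temp, precip)
  })
  attr(out, "n_capped") <- n_capped
  out
}

#' Reference-anchored principal component projection
#'
#' Standardises features with the reference table's means and standard
#' deviations and extracts the first `k` principal axes from the reference
#' only; any table projected through the returned object uses those same
#' loadings, so focal and reference periods live in one common space.
#'
#' @param reference feature table (data.frame or matrix).
#' @param k number of axes (default 3).
#' @return an object of class `pca_projection`; use `project(obj, table)`.
#' @export
pca_reference <- function(reference, k = 3) {
  X <- feature_matrix(as.data.frame(reference))
  if (ncol(X) < k) stopf("need at least k = %d feature columns", k)
  if (nrow(X) < k + 1) stopf("need at least k + 1 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stopf("rank-deficient reference: constant feature column")
  Z <- scale(X, ctr, scl)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (ncol(pc$rotation) < k) stopf("rank-deficient reference")
  structure(list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev, k = k),
            class = "pca_projection")
}

#' Project a feature table with fixed loadings
#'
#' @param projection a [pca_reference()] result.
#' @param table feature table.
#' @return a numeric matrix with `k` columns.
#' @export
project <- function(projection, table) {
  stopifnot(inherits(projection, "pca_projection"))
  X <- feature_matrix(as.data.frame(table))
  scale(X, projection$center, projection$scale) %*% projection$rotation
}

# Product-Gaussian KDE density of points x (m x d) given kernel points
# (n x d) and per-dimension bandwidths.
kde_density <- function(x, kernel_points, bw) {
  x <- as.matrix(x)
  kp <- sweep(kernel_points, 2, bw, "/")
  xs <- sweep(x, 2, bw, "/")
  d2 <- outer(rowSums(xs^2), rowSums(kp^2), "+") - 2 * tcrossprod(xs, kp)
  rowMeans(exp(-0.5 * pmax(d2, 0))) / ((2 * pi)^(ncol(x) / 2) * prod(bw))
}

silverman_bw <- function(X) {
  n <- nrow(X); d <- ncol(X)
  apply(X, 2, stats::sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
}

#' Bootstrapped kernel-density hypervolumes
#'
#' For each bootstrap replicate: resample the rows with replacement, fit a
#' product-Gaussian KDE with `bw_mult` times the Silverman bandwidths, set
#' the boundary density level so that the region encloses a `quantile`
#' fraction of the original points, and characterise the region by a cloud
#' of points drawn uniformly inside it (rejection sampling in the
#' bandwidth-expanded bounding box). The region volume is the box volume
#' times the acceptance rate. The default `bw_mult = 2` oversmooths
#' relative to Silverman's density-estimation optimum deliberately: region
#' delineation needs a smooth boundary, and the doubled bandwidth makes the
#' estimated 95% region of a multivariate normal sample match its
#' closed-form volume to a few percent, where Silverman bandwidths leave it
#' ~15% small.
#'
#' @param points matrix of observations in the (projected) climate space.
#' @param n_boot number of bootstrap hypervolumes.
#' @param quantile fraction of the sample the region must contain.
#' @param cloud_size interior cloud size per hypervolume.
#' @param bw_mult bandwidth multiplier on the Silverman rule.
#' @param seed stage seed.
#' @return a list of `hypervolume` objects (fields `kernel_points`, `bw`,
#'   `level`, `cloud`, `volume`, `dim`).
#' @export
bootstrap_hypervolume <- function(points, n_boot = 20, quantile = 0.95,
                                  cloud_size = 1000, bw_mult = 2,
                                  seed = NULL) {
  X <- as.matrix(points)
  d <- ncol(X)
  if (nrow(unique(X)) < d + 1) {
    stopf("degenerate point set: need more than d + 1 distinct points")
  }
  if (nrow(X) < 50) warning("fewer than 50 points: hypervolumes will be unstable")
  with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
      kp <- X[idx, , drop = FALSE]
      bw <- silverman_bw(kp) * bw_mult
      if (any(bw <= 0)) stopf("degenerate bootstrap sample: zero bandwidth")
      # the boundary level is calibrated on the densities of the original
      # (pre-bootstrap) points: resampled points carry duplicates whose
      # inflated densities would push the level up and shrink the region
      level <- stats::quantile(kde_density(X, kp, bw), 1 - quantile,
                               names = FALSE)
      lo <- apply(kp, 2, min) - 3 * bw
      hi <- apply(kp, 2, max) + 3 * bw
      box_vol <- prod(hi - lo)
      accepted <- matrix(numeric(0), 0, d)
      tried <- 0L
      batch <- max(4L * cloud_size, 2000L)
      for (it in seq_len(200L)) {
        cand <- sapply(seq_len(d), function(j)
          stats::runif(batch, lo[j], hi[j]))
        keep <- kde_density(cand, kp, bw) >= level
        accepted <- rbind(accepted, cand[keep, , drop = FALSE])
        tried <- tried + batch
        if (nrow(accepted) >= cloud_size) break
      }
      if (nrow(accepted) < d + 1) {
        stopf("hypervolume rejection sampling failed (acceptance ~ 0)")
      }
      structure(list(kernel_points = kp, bw = bw, level = level,
                     cloud = accepted[seq_len(min(cloud_size,
                                                  nrow(accepted))), ,
                                      drop = FALSE],
                     volume = box_vol * nrow(accepted) / tried,
                     dim = d),
                class = "hypervolume")
    })
  })
}

#' Sørensen overlap between two hypervolumes
#'
#' `2 V(A ∩ B) / (V(A) + V(B))`, with the intersection volume estimated
#' symmetrically by cross point-in-region tests: the fraction of A's
#' interior cloud lying inside B's region scaled by V(A), averaged with the
#' mirrored estimate.
#'
#' @param A,B `hypervolume` objects in the same projected space.
#' @return overlap in `[0, 1]`.
#' @export
overlap_sorensen <- function(A, B) {
  stopifnot(inherits(A, "hypervolume"), inherits(B, "hypervolume"))
  if (A$dim != B$dim) stopf("hypervolume dimension mismatch")
  fA <- mean(kde_density(A$cloud, B$kernel_points, B$bw) >= B$level)
  fB <- mean(kde_density(B$cloud, A$kernel_points, A$bw) >= A$level)
  v_int <- (fA * A$volume + fB * B$volume) / 2
  min(max(2 * v_int / (A$volume + B$volume), 0), 1)
}

#' Climatic dissimilarity between a focal and a reference period
#'
#' Projects both feature tables into a common `k`-dimensional principal
#' component space (loadings from the pooled sample by default, or from the
#' reference only), builds `n_boot` bootstrapped hypervolumes per period,
#' and summarises `1 - Sørensen overlap` over all `n_boot x n_boot` pairs.
#'
#' @param focal,reference seasonal feature tables (see
#'   [seasonal_features()]), or matrices already in feature columns.
#' @param n_boot bootstrap hypervolumes per period (20 x 20 pairs by
#'   default).
#' @param k principal axes.
#' @param cloud_size interior cloud size per hypervolume.
#' @param pca `"pooled"` (default) or `"reference"` loadings.
#' @param n_sample optional row subsample size per period (for large
#'   cell-by-year tables).
#' @param seed stage seed.
#' @return an object of class `dissimilarity_estimate`: list with `mean`,
#'   `sd`, `n_pairs`, `n_boot`.
#' @export
dissimilarity <- function(focal, reference, n_boot = 20, k = 3,
                          cloud_size = 1000,
                          pca = c("pooled", "reference"),
                          n_sample = NULL, seed = NULL) {
  pca <- match.arg(pca)
  Xf <- feature_matrix(as.data.frame(focal))
  Xr <- feature_matrix(as.data.frame(reference))
  with_seed(seed, {
    if (!is.null(n_sample)) {
      if (nrow(Xf) > n_sample) Xf <- Xf[sample.int(nrow(Xf), n_sample), ]
      if (nrow(Xr) > n_sample) Xr <- Xr[sample.int(nrow(Xr), n_sample), ]
    }
    proj <- pca_reference(if (pca == "pooled") rbind(Xf, Xr) else Xr, k = k)
    Pf <- project(proj, Xf)
    Pr <- project(proj, Xr)
    hf <- bootstrap_hypervolume(Pf, n_boot = n_boot, cloud_size = cloud_size,
                                seed = NULL)
    hr <- bootstrap_hypervolume(Pr, n_boot = n_boot, cloud_size = cloud_size,
                                seed = NULL)
    ov <- vapply(hf, function(a) vapply(hr, function(b)
      overlap_sorensen(a, b), numeric(1)), numeric(length(hr)))
    dis <- 1 - as.numeric(ov)
    structure(list(mean = mean(dis), sd = stats::sd(dis),
                   n_pairs = length(dis), n_boot = n_boot),
              class = "dissimilarity_estimate")
  })
}

#' @exportS3Method base::print
print.dissimilarity_estimate <- function(x, ...) {
  cat(sprintf("<dissimilarity> mean %.3f, sd %.3f (%d hypervolume pairs)\n",
              x$mean, x$sd, x$n_pairs))
  invisible(x)
}

#' Mahalanobis climate novelty
#'
#' For every focal climate vector, the minimum Mahalanobis distance to any
#' vector of the reference pool, using the reference covariance (regularised
#' by `1e-6 I` if singular).
#'
#' @param focal,reference numeric matrices with matching columns.
#' @return numeric vector of per-focal-row distances.
#' @export
mahalanobis_novelty <- function(focal, reference) {
  F <- as.matrix(focal); R <- as.matrix(reference)
  if (ncol(F) != ncol(R)) stopf("column mismatch")
  S <- stats::cov(R)
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) S <- S + diag(1e-6, ncol(S))
  L <- tryCatch(chol(S), error = function(e)
    stopf("reference covariance singular after regularisation"))
  Wf <- F %*% backsolve(L, diag(ncol(S)))
  Wr <- R %*% backsolve(L, diag(ncol(S)))
  d2 <- outer(rowSums(Wf^2), rowSums(Wr^2), "+") - 2 * tcrossprod(Wf, Wr)
  sqrt(pmax(apply(d2, 1, min), 0))
}
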
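# Surrogate suitability models: a correlative classifier calibrated on
# occurrences, and inverse calibration of the mechanistic species.

CLIMATE_COVARIATES <- c("tmin_winter", "gdd", "precip_total",
                        "water_balance_summer")

# Covariate matrix for a set of coarse cells (data.frame with row, col).
covariates_at <- function(slice, cells) {
  idx <- cbind(cells$row, cells$col)
  out <- vapply(CLIMATE_COVARIATES, function(v) slice[[v]][idx],
                numeric(nrow(cells)))
  colnames(out) <- CLIMATE_COVARIATES
  out
}

all_cells <- function(config) {
  expand.grid(row = seq_len(config$n_rows), col = seq_len(config$n_cols),
              KEEP.OUT.ATTRS = FALSE)
}

# Raw polynomial expansion: linear terms, squares, pairwise interactions.
poly_features <- function(X, degree = 2L) {
  X <- as.matrix(X)
  feats <- X
  if (degree >= 2L) {
    sq <- X^2
    colnames(sq) <- paste0(colnames(X), "_sq")
    p <- ncol(X)
    inter <- NULL
    if (p >= 2L) {
      pairs <- utils::combn(p, 2L)
      inter <- X[, pairs[1L, ], drop = FALSE] * X[, pairs[2L, ], drop = FALSE]
      colnames(inter) <- paste0(colnames(X)[pairs[1L, ]], "_x_",
                                colnames(X)[pairs[2L, ]])
    }
    feats <- cbind(feats, sq, inter)
  }
  feats
}

#' Sample background cells
#'
#' Uniform random coarse cells used as pseudo-absences when calibrating the
#' correlative surrogate (the desk-scale analogue of sampling tens of
#' thousands of background points over a study area).
#'
#' @param config a [landscape_config()].
#' @param n number of points (>= 1, at most 100x the number of cells).
#' @param replace sample with replacement (default). With `replace = FALSE`
#'   and `n` equal to the number of cells, every cell is returned once.
#' @param seed stage seed.
#' @return a data.frame with columns `row`, `col`.
#' @export
sample_background <- function(config, n, replace = TRUE, seed = NULL) {
  ncell <- config$n_rows * config$n_cols
  if (n < 1) stopf("n must be >= 1")
  if (n > 100 * ncell) stopf("n exceeds the background cap (100 x cells)")
  if (!replace && n > ncell) stopf("cannot sample %d cells without replacement", n)
  seed <- seed %||% derive_seed(config$seed, 2L)
  cells <- with_seed(seed, sample.int(ncell, n, replace = replace))
  data.frame(row = ((cells - 1L) %% config$n_rows) + 1L,
             col = ((cells - 1L) %/% config$n_rows) + 1L)
}

#' Fit the correlative surrogate
#'
#' A lasso-regularised logistic regression (via [glmnet::cv.glmnet()]) on
#' standardised degree-`degree` polynomial climate features, trained on
#' presence cells versus background cells of the reference-period slice(s).
#' This single regularised linear-in-features classifier stands in for the
#' usual ensemble of correlative SDM algorithms: what the analysis needs is
#' the correlative/mechanistic contrast, not an inter-algorithm spread.
#'
#' @param presences,background data.frames with `row`, `col` coarse cells.
#' @param slices a `climate_slice` or list of them (the calibration period);
#'   presences and background are evaluated against each slice.
#' @param degree polynomial feature degree (default 2).
#' @param seed seed for the internal cross-validation folds.
#' @return an object of class `correlative_surrogate` with elements
#'   `coefficients`, `center`, `scale`, `degree`, `training_auc`.
#' @export
fit_correlative <- function(presences, background, slices, degree = 2L,
                            seed = NULL) {
  if (inherits(slices, "climate_slice")) slices <- list(slices)
  if (nrow(presences) < 20) stopf("need at least 20 presences")
  if (nrow(background) < 1) stopf("need background points")
  X <- do.call(rbind, lapply(slices, function(s) {
    rbind(covariates_at(s, presences), covariates_at(s, background))
  }))
  y <- rep(rep(c(1L, 0L), c(nrow(presences), nrow(background))),
           length(slices))
  if (length(unique(y)) < 2L) stopf("degenerate single-class training data")
  F <- poly_features(X, degree)
  ctr <- colMeans(F)
  scl <- apply(F, 2, stats::sd)
  scl[scl == 0] <- 1
  Fs <- scale(F, ctr, scl)
  fit <- with_seed(seed %||% 1L,
                   glmnet::cv.glmnet(Fs, y, family = "binomial", alpha = 1,
                                     nfolds = 5, standardize = FALSE))
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
  scores <- stats::plogis(beta[1L] + Fs %*% beta[-1L])[, 1L]
  structure(list(coefficients = beta, center = ctr, scale = scl,
                 degree = degree, feature_names = colnames(F),
                 training_auc = auc_mw(scores, y)),
            class = "correlative_surrogate")
}

#' @exportS3Method base::print
print.correlative_surrogate <- function(x, ...) {
  cat(sprintf(
    "<correlative_surrogate> degree-%d features, %d nonzero coefs, training AUC %.3f\n",
    x$degree, sum(x$coefficients[-1L] != 0), x$training_auc))
  invisible(x)
}

#' Predict correlative suitability for a climate slice
#'
#' @param object a `correlative_surrogate`.
#' @param slice a `climate_slice`.
#' @param species label to attach to the output map.
#' @param ... unused.
#' @return a `suitability_map` of probabilities in `[0, 1]`.
#' @export
predict.correlative_surrogate <- function(object, slice, species = "species",
                                          ...) {
  nr <- nrow(slice$tmin_winter); nc <- ncol(slice$tmin_winter)
  cells <- all_cells(structure(list(n_rows = nr, n_cols = nc),
                               class = "landscape_config"))
  F <- poly_features(covariates_at(slice, cells), object$degree)
  Fs <- scale(F, object$center, object$scale)
  p <- stats::plogis(object$coefficients[1L] +
                       Fs %*% object$coefficients[-1L])[, 1L]
  new_suitability_map(matrix(p, nr, nc), species, slice$time_bp)
}

# Scores of any surrogate at a set of cells.
surrogate_scores <- function(model, slice, cells) {
  if (inherits(model, "virtual_species")) {
    X <- covariates_at(slice, cells)
    fitness_from_covariates(X[, "tmin_winter"], X[, "water_balance_summer"],
                            X[, "gdd"], model)
  } else if (inherits(model, "correlative_surrogate")) {
    m <- predict(model, slice)
    m$values[cbind(cells$row, cells$col)]
  } else {
    stopf("unknown surrogate model class")
  }
}

#' Default inverse-calibration bounds around a template species
#'
#' @param template a [virtual_species()].
#' @return a 2-row matrix (lower, upper) over the six parameters.
#' @export
default_calibration_bounds <- function(template) {
  p <- species_params(template)
  lower <- c(frost_t50 = p[["frost_t50"]] - 15, frost_slope = 0.3,
             drought_w50 = p[["drought_w50"]] - 150, drought_slope = 3,
             gdd_req = max(p[["gdd_req"]] - 700, 0), gdd_slope = 20)
  upper <- c(frost_t50 = p[["frost_t50"]] + 15, frost_slope = 10,
             drought_w50 = p[["drought_w50"]] + 150, drought_slope = 100,
             gdd_req = p[["gdd_req"]] + 700, gdd_slope = 600)
  rbind(lower = lower, upper = upper)
}

#' Inverse-calibrate the mechanistic species on occurrence data
#'
#' Estimates the six response-curve parameters by maximising the AUC of
#' [process_fitness()] scores against presence/background labels on the
#' calibration slice, using a bounded (mu, lambda) Gaussian evolution
#' strategy (a derivative-free optimiser in the spirit of the evolution
#' strategies used to calibrate process-explicit models on occurrences).
#' Among `n_restarts` independent runs, the best-AUC run is retained.
#'
#' @param template a [virtual_species()]; supplies the parameter names,
#'   default bounds and one initial centre.
#' @param presences,background data.frames with `row`, `col`.
#' @param slice calibration `climate_slice`.
#' @param bounds 2 x 6 matrix of lower/upper parameter bounds
#'   (default [default_calibration_bounds()]).
#' @param budget total objective evaluations per restart (>= 100 advised;
#'   a budget smaller than one population returns the best of the initial
#'   population).
#' @param n_restarts independent restarts (first starts at the template,
#'   later ones at random points in the bounds).
#' @param lambda,mu population and parent counts per generation.
#' @param sigma0 initial step size, as a fraction of each bound range.
#' @param seed stage seed.
#' @return a list with `species` (fitted [virtual_species()]), `auc`,
#'   `n_eval`, and `restart_aucs`.
#' @export
inverse_calibrate <- function(template, presences, background, slice,
                              bounds = default_calibration_bounds(template),
                              budget = 400, n_restarts = 2, lambda = 12,
                              mu = 3, sigma0 = 0.3, seed = NULL) {
  stopifnot(inherits(template, "virtual_species"))
  cells <- rbind(presences[c("row", "col")], background[c("row", "col")])
  labels <- rep(c(1L, 0L), c(nrow(presences), nrow(background)))
  lo <- bounds["lower", ]; hi <- bounds["upper", ]
  rng <- hi - lo
  objective <- function(par) {
    sp <- species_from_params(par, template$name)
    auc_mw(surrogate_scores(sp, slice, cells), labels)
  }
  to_unit <- function(par) (par - lo) / rng
  from_unit <- function(u) lo + pmin(pmax(u, 0), 1) * rng

  run_once <- function(centre_u) {
    sigma <- sigma0
    best <- list(u = centre_u, auc = -Inf)
    n_eval <- 0L
    centre <- centre_u
    while (n_eval < budget) {
      n_off <- min(lambda, budget - n_eval)
      off <- matrix(stats::rnorm(n_off * length(centre), 0, sigma),
                    n_off, length(centre), byrow = FALSE)
      off <- sweep(off, 2, centre, "+")
      off <- pmin(pmax(off, 0), 1)
      aucs <- apply(off, 1, function(u) objective(from_unit(
        stats::setNames(u, names(lo)))))
      n_eval <- n_eval + n_off
      ord <- order(aucs, decreasing = TRUE)
      if (aucs[ord[1L]] > best$auc) {
        best <- list(u = off[ord[1L], ], auc = aucs[ord[1L]])
        sigma <- min(sigma * 1.1, 0.5)
      } else {
        sigma <- max(sigma * 0.8, 0.02)
      }
      keep <- ord[seq_len(min(mu, n_off))]
      centre <- colMeans(off[keep, , drop = FALSE])
    }
    c(best, n_eval = n_eval)
  }

  seed <- seed %||% 1L
  runs <- with_seed(seed, {
    starts <- c(list(to_unit(species_params(template))),
                replicate(max(n_restarts - 1L, 0L),
                          stats::runif(length(lo)), simplify = FALSE))
    lapply(starts[seq_len(max(n_restarts, 1L))], run_once)
  })
  aucs <- vapply(runs, `[[`, numeric(1), "auc")
  best <- runs[[which.max(aucs)]]
  par <- stats::setNames(from_unit(best$u), names(lo))
  list(species = species_from_params(par, paste0(template$name, "_fitted")),
       auc = best$auc, n_eval = sum(vapply(runs, `[[`, numeric(1), "n_eval")),
       restart_aucs = aucs)
}

#' Threshold maximising the true skill statistic
#'
#' Scans every observed score value as a candidate threshold (presence
#' predicted where `score >= tau`) and returns the smallest value maximising
#' TSS = sensitivity + specificity - 1. The smallest maximiser is the most
#' permissive presence rule among the ties.
#'
#' @param scores numeric model outputs.
#' @param labels 0/1 observed presence.
#' @return the threshold, with the achieved TSS attached as attribute `tss`.
#' @export
max_tss_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]
  n1 <- sum(y); n0 <- length(y) - n1
  # For candidate tau = s[i]: predictions are positive for indices >= i.
  pos_ge <- rev(cumsum(rev(y)))          # true positives at tau = s[i]
  neg_ge <- rev(cumsum(rev(1L - y)))     # false positives at tau = s[i]
  tss_vals <- pos_ge / n1 + (n0 - neg_ge) / n0 - 1
  keep <- !duplicated(s)  # first index of each distinct score run
  s <- s[keep]; tss_vals <- tss_vals[keep]
  best <- max(tss_vals)
  tau <- min(s[tss_vals >= best - 1e-12])
  structure(tau, tss = best)
}

#' Environmental-block cross-validation of the correlative surrogate
#'
#' Builds `k` folds as contiguous blocks in climate space: all calibration
#' points are projected on the principal components of their standardised
#' covariates and clustered with k-means. Each block is held out once; the
#' surrogate is refitted on the remaining blocks and scored by AUC on the
#' held-out block. A fold whose test set contains a single class (or whose
#' training set cannot be fitted) is reported as missing, not dropped.
#'
#' @param presences,background data.frames with `row`, `col`.
#' @param slice calibration `climate_slice`.
#' @param k number of folds (>= 2).
#' @param degree feature degree passed to [fit_correlative()].
#' @param seed stage seed (k-means and glmnet folds).
#' @return a data.frame with columns `fold`, `n_test`, `auc` (NA for missing
#'   folds) and attribute `missing` listing unusable folds.
#' @export
env_block_cv <- function(presences, background, slice, k = 5, degree = 2L,
                         seed = NULL) {
  if (k < 2) stopf("k must be >= 2")
  pts <- rbind(presences[c("row", "col")], background[c("row", "col")])
  y <- rep(c(1L, 0L), c(nrow(presences), nrow(background)))
  X <- covariates_at(slice, pts)
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  pcs <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$x
  seed <- seed %||% 1L
  cl <- with_seed(seed, stats::kmeans(pcs, centers = k, nstart = 5,
                                      iter.max = 50)$cluster)
  res <- data.frame(fold = seq_len(k), n_test = NA_integer_, auc = NA_real_)
  missing <- integer(0)
  for (f in seq_len(k)) {
    test <- cl == f
    res$n_test[f] <- sum(test)
    y_test <- y[test]
    if (length(unique(y_test)) < 2L) { missing <- c(missing, f); next }
    tr_p <- pts[!test & y == 1L, , drop = FALSE]
    tr_b <- pts[!test & y == 0L, , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(fit_correlative(tr_p, tr_b, slice, degree = degree,
                                       seed = derive_seed(seed, f))),
      error = function(e) NULL)
    if (is.null(fit)) { missing <- c(missing, f); next }
    sc <- surrogate_scores(fit, slice, pts[test, , drop = FALSE])
    res$auc[f] <- auc_mw(sc, y_test)
  }
  attr(res, "missing") <- missing
  res
}
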
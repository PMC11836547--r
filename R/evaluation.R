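# Hindcast scoring: confusion matrices over data cells, Sørensen and TSS,
# transferability, and the rank-based comparative statistics.

#' Confusion matrix of a presence hindcast against the pollen grid
#'
#' Counts are taken only over cells where pollen-derived presence or absence
#' is available (the `presence_grid` rows); cells without data never enter
#' the evaluation.
#'
#' @param pred logical coarse matrix of predicted presence.
#' @param obs a `presence_grid` ([grid_presence()]).
#' @param bin,taxon optional filters on the grid rows.
#' @return an object of class `confusion_matrix`: list with `tp`, `fp`,
#'   `fn`, `tn`, `n`.
#' @export
confusion <- function(pred, obs, bin = NULL, taxon = NULL) {
  rows <- obs
  if (!is.null(bin)) rows <- rows[rows$bin_centre_bp == bin, , drop = FALSE]
  if (!is.null(taxon)) rows <- rows[rows$taxon == taxon, , drop = FALSE]
  if (!nrow(rows)) {
    stopf("no data cells to evaluate", class = "paleoshift_empty_evaluation")
  }
  dims <- attr(obs, "dims")
  if (!is.null(dims) && !all(dim(pred) == dims)) {
    stopf("prediction grid does not match the presence grid")
  }
  p <- pred[cbind(rows$row, rows$col)]
  o <- rows$state == "present"
  structure(list(tp = sum(p & o), fp = sum(p & !o),
                 fn = sum(!p & o), tn = sum(!p & !o), n = nrow(rows)),
            class = "confusion_matrix")
}

#' @exportS3Method base::print
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion> tp %d fp %d fn %d tn %d (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Sørensen similarity index of a confusion matrix
#'
#' `2 tp / (2 tp + fp + fn)`. True negatives do not enter, so the index is
#' not inflated by large numbers of correctly predicted absences — the
#' reason it suits sparse fossil-presence evaluations.
#'
#' @param cm a `confusion_matrix`.
#' @return value in `[0, 1]`.
#' @export
sorensen_index <- function(cm) {
  with(cm, {
    if (tp + fp + fn == 0) {
      stopf("Sørensen undefined: tp + fp + fn = 0",
            class = "paleoshift_empty_evaluation")
    }
    2 * tp / (2 * tp + fp + fn)
  })
}

#' True skill statistic of a confusion matrix
#'
#' Sensitivity + specificity - 1.
#'
#' @param cm a `confusion_matrix`.
#' @return value in `[-1, 1]`.
#' @export
tss <- function(cm) {
  with(cm, {
    if (tp + fn == 0 || tn + fp == 0) {
      stopf("TSS undefined: a margin of the confusion matrix is zero",
            class = "paleoshift_empty_evaluation")
    }
    tp / (tp + fn) + tn / (tn + fp) - 1
  })
}

#' Transferability: relative change in performance versus the reference
#'
#' `(perf - perf_reference) / perf_reference`; negative values mean the
#' model performs worse in the hindcast period than in its calibration
#' period.
#'
#' @param perf,perf_reference performance values (reference > 0).
#' @return relative change.
#' @export
transferability <- function(perf, perf_reference) {
  if (any(perf_reference == 0)) stopf("zero reference performance")
  (perf - perf_reference) / perf_reference
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-square reference with k - 1 degrees of freedom), with the degenerate
#' all-equal case returned explicitly as H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, >= 2 values each).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stopf("need >= 2 groups with >= 2 values each")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Conover-Iman pairwise post hoc comparisons
#'
#' Rank-based pairwise t statistics computed after a Kruskal-Wallis test on
#' the same data:
#' `t_ij = (Rbar_i - Rbar_j) / sqrt(S^2 ((N - 1 - H) / (N - k)) (1/n_i + 1/n_j))`
#' with `S^2` the pooled variance of the (mid)ranks, compared to a Student
#' t distribution with `N - k` degrees of freedom (two-sided). The sign
#' convention is first-listed group minus second. P values are unadjusted by
#' default; any [stats::p.adjust()] method can be requested.
#'
#' @param groups named list of numeric vectors.
#' @param adjust multiple-testing adjustment method (default `"none"`).
#' @return a data.frame with `group1`, `group2`, `t`, `p`, `p_adjusted`.
#' @export
conover_iman <- function(groups, adjust = "none") {
  if (any(lengths(groups) < 2L)) stopf("every group needs >= 2 values")
  kw <- kruskal_wallis(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  N <- length(x); k <- length(groups)
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale2 <- S2 * (N - 1 - kw$H) / (N - k)
  pairs <- utils::combn(names(groups), 2L)
  t_stat <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se <- sqrt(scale2 * (1 / n[[i1]] + 1 / n[[i2]]))
    t_stat[j] <- if (se == 0) 0 else (rbar[[i1]] - rbar[[i2]]) / se
    p[j] <- 2 * stats::pt(abs(t_stat[j]), df = N - k, lower.tail = FALSE)
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], t = t_stat, p = p,
             p_adjusted = stats::p.adjust(p, method = adjust))
}
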
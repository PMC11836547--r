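# Independent brute-force oracles used by the derived-value tests. These
# deliberately use naive loops / alternative algorithms, never the package's
# own code paths.

bf_confusion <- function(pred, obs_rows) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(obs_rows))) {
    p <- pred[obs_rows$row[i], obs_rows$col[i]]
    o <- obs_rows$state[i] == "present"
    if (p && o) tp <- tp + 1L
    else if (p && !o) fp <- fp + 1L
    else if (!p && o) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

bf_grid_presence <- function(site_presence, nr, nc) {
  out <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    for (b in unique(site_presence$bin_centre_bp)) {
      for (tx in unique(site_presence$taxon)) {
        idx <- which(floor(site_presence$y) + 1 == r &
                       floor(site_presence$x) + 1 == cc &
                       site_presence$bin_centre_bp == b &
                       site_presence$taxon == tx)
        if (!length(idx)) next
        out[[length(out) + 1L]] <- data.frame(
          row = r, col = cc, bin_centre_bp = b, taxon = tx,
          state = if (any(site_presence$present[idx])) "present" else "absent")
      }
    }
  }
  do.call(rbind, out)
}

bf_mahalanobis_min <- function(focal, reference, S) {
  Sinv <- solve(S)
  out <- numeric(nrow(focal))
  for (i in seq_len(nrow(focal))) {
    best <- Inf
    for (j in seq_len(nrow(reference))) {
      v <- focal[i, ] - reference[j, ]
      best <- min(best, sqrt(drop(t(v) %*% Sinv %*% v)))
    }
    out[i] <- best
  }
  out
}

bf_max_tss <- function(scores, labels) {
  best_tss <- -Inf; best_tau <- Inf
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  for (tau in sort(unique(scores))) {
    pred <- scores >= tau
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    tt <- sens + spec - 1
    if (tt > best_tss + 1e-12) { best_tss <- tt; best_tau <- tau }
  }
  list(tau = best_tau, tss = best_tss)
}

bf_kruskal_H <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x); N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  # tie correction
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

bf_conover <- function(groups) {
  x <- unlist(groups); g <- rep(names(groups), lengths(groups))
  r <- rank(x); N <- length(x); k <- length(groups)
  H <- bf_kruskal_H(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  res <- list()
  nms <- names(groups)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    na <- sum(g == nms[a]); nb <- sum(g == nms[b])
    num <- mean(r[g == nms[a]]) - mean(r[g == nms[b]])
    den <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / na + 1 / nb))
    tt <- num / den
    res[[length(res) + 1L]] <- data.frame(
      group1 = nms[a], group2 = nms[b], t = tt,
      p = 2 * pt(abs(tt), N - k, lower.tail = FALSE))
  }
  do.call(rbind, res)
}

# Manhattan-ball (diamond) breadth-first-search oracle for the deterministic
# rook kernel.
bf_diamond <- function(nr, nc, r0, c0, steps) {
  outer(seq_len(nr), seq_len(nc),
        function(i, j) abs(i - r0) + abs(j - c0) <= steps)
}

# Independent dispersal simulator: explicit shift-and-accumulate over kernel
# offsets (no FFT), synchronous annual update, establishment prob p.
oracle_disperse_run <- function(occ, p, kernel_mat, steps) {
  R <- (nrow(kernel_mat) - 1) %/% 2
  nr <- nrow(occ); nc <- ncol(occ)
  for (s in seq_len(steps)) {
    log_miss <- matrix(0, nr, nc)
    for (di in -R:R) for (dj in -R:R) {
      k <- kernel_mat[di + R + 1, dj + R + 1]
      if (k <= 0) next
      # contribution of sources at offset (-di,-dj) to each cell
      src <- matrix(FALSE, nr, nc)
      ri <- max(1, 1 - di):min(nr, nr - di)
      cj <- max(1, 1 - dj):min(nc, nc - dj)
      src[ri, cj] <- occ[ri + di, cj + dj]
      log_miss <- log_miss + log1p(-min(k, 1 - 1e-15)) * src
    }
    arrive <- 1 - exp(log_miss)
    newly <- !occ & matrix(runif(nr * nc), nr, nc) < p * arrive
    occ <- occ | newly
  }
  occ
}

# Chebyshev dilation of an occupancy mask by radius R (independent path for
# the spread-rate hard bound).
bf_dilate <- function(occ, R) {
  nr <- nrow(occ); nc <- ncol(occ)
  out <- matrix(FALSE, nr, nc)
  for (di in -R:R) for (dj in -R:R) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    cj <- max(1, 1 - dj):min(nc, nc - dj)
    sub <- matrix(FALSE, nr, nc)
    sub[ri, cj] <- occ[ri + di, cj + dj]
    out <- out | sub
  }
  out
}

# Maximum-likelihood plain beta regression (logit link, precision phi),
# coded independently for the interior-only limiting case.
oracle_beta_regression <- function(y, x) {
  nll <- function(th) {
    mu <- plogis(th[1] + th[2] * x)
    phi <- exp(th[3])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  opt <- optim(c(0, 0, log(5)), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  list(slope = opt$par[2], slope_se = se[2])
}

# Grid-integration oracle for the Sørensen overlap of two fixed KDE regions.
oracle_overlap_grid <- function(A, B, n_grid = 45) {
  lo <- pmin(apply(A$kernel_points, 2, min) - 3 * A$bw,
             apply(B$kernel_points, 2, min) - 3 * B$bw)
  hi <- pmax(apply(A$kernel_points, 2, max) + 3 * A$bw,
             apply(B$kernel_points, 2, max) + 3 * B$bw)
  axes <- lapply(seq_along(lo), function(j)
    seq(lo[j], hi[j], length.out = n_grid))
  gr <- as.matrix(expand.grid(axes))
  cellv <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
  kde_at <- function(pts, H) {
    # independent KDE evaluation: explicit per-dimension normal products
    out <- numeric(nrow(pts))
    for (j in seq_len(nrow(H$kernel_points))) {
      term <- rep(1, nrow(pts))
      for (d in seq_len(ncol(pts))) {
        term <- term * dnorm(pts[, d], H$kernel_points[j, d], H$bw[d])
      }
      out <- out + term
    }
    out / nrow(H$kernel_points)
  }
  inA <- kde_at(gr, A) >= A$level
  inB <- kde_at(gr, B) >= B$level
  vA <- sum(inA) * cellv; vB <- sum(inB) * cellv
  vI <- sum(inA & inB) * cellv
  2 * vI / (vA + vB)
}
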
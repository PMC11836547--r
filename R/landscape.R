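#' Landscape configuration
#'
#' Defines the two nested grids the pipeline works on: a coarse grid on which
#' climate, suitability and pollen presence live (the analogue of a 0.25
#' degree evaluation grid) and a fine grid on which dispersal is simulated
#' (the analogue of a 500 m migration grid). The fine grid subdivides every
#' coarse cell into `fine_per_coarse` x `fine_per_coarse` cells.
#'
#' @param n_rows,n_cols coarse grid dimensions (each >= 2). Row 1 is the cold
#'   (northern) edge of the domain.
#' @param coarse_cell_km edge length of a coarse cell, km.
#' @param fine_per_coarse integer subdivision factor (>= 1).
#' @param elevation optional `n_rows` x `n_cols` matrix of coarse-cell mean
#'   elevations in metres; defaults to a flat domain at 200 m.
#' @param seed integer seed associated with the landscape; generators derive
#'   their stage seeds from it unless given their own.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(n_rows, n_cols, coarse_cell_km = 25,
                             fine_per_coarse = 4L, elevation = NULL,
                             seed = 1L) {
  if (n_rows < 2 || n_cols < 2) stopf("n_rows and n_cols must be >= 2")
  fine_per_coarse <- as.integer(fine_per_coarse)
  if (fine_per_coarse < 1L) stopf("fine_per_coarse must be >= 1")
  if (is.null(elevation)) {
    elevation <- matrix(200, n_rows, n_cols)
  }
  if (!all(dim(elevation) == c(n_rows, n_cols))) {
    stopf("elevation must be an n_rows x n_cols matrix")
  }
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    coarse_cell_km = coarse_cell_km, fine_per_coarse = fine_per_coarse,
    elevation = elevation, seed = as.integer(seed)
  ), class = "landscape_config")
}

#' @exportS3Method base::print
print.landscape_config <- function(x, ...) {
  cat(sprintf(
    "<landscape_config> %d x %d coarse cells (%g km), fine factor %d (%d x %d fine)\n",
    x$n_rows, x$n_cols, x$coarse_cell_km, x$fine_per_coarse,
    x$n_rows * x$fine_per_coarse, x$n_cols * x$fine_per_coarse))
  invisible(x)
}

fine_dim <- function(config) {
  c(config$n_rows, config$n_cols) * config$fine_per_coarse
}

#' Broadcast a coarse-grid matrix to the fine grid
#'
#' Every fine cell receives the value of its enclosing coarse cell.
#'
#' @param mat coarse matrix.
#' @param f integer nesting factor.
#' @return a matrix with `f`-times the rows and columns of `mat`.
#' @export
broadcast_to_fine <- function(mat, f) {
  f <- as.integer(f)
  mat[rep(seq_len(nrow(mat)), each = f),
      rep(seq_len(ncol(mat)), each = f), drop = FALSE]
}

# Per-block counts of TRUE fine cells, as a coarse matrix.
block_counts <- function(fine, f) {
  f <- as.integer(f)
  if (nrow(fine) %% f != 0L || ncol(fine) %% f != 0L) {
    stopf("fine grid (%d x %d) does not nest with factor %d",
          nrow(fine), ncol(fine), f)
  }
  gr <- rep(seq_len(nrow(fine) %/% f), each = f)
  gc <- rep(seq_len(ncol(fine) %/% f), each = f)
  out <- t(rowsum(t(rowsum(fine + 0, gr)), gc))
  dimnames(out) <- NULL
  out
}
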
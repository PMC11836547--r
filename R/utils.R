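# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit. Every stochastic stage of the
#' pipeline goes through this helper with its own named seed, so no stage
#' perturbs another's stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483399 + 1)
}

stopf <- function(fmt, ..., class = NULL) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "paleoshift_error")))
}

# Mann-Whitney AUC (midranks handle ties). Used heavily inside inverse
# calibration, hence not delegated to pROC; a unit test cross-checks the two.
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# 2-D "same" linear convolution via zero-padded FFT. `k` must be a square
# (2R+1) x (2R+1) matrix. Returns a matrix the size of `x` where entry (i,j)
# = sum over offsets of k[offset] * x[(i,j) - offset].
conv2d_same <- function(x, k, k_fft = NULL, pad = NULL) {
  kr <- (nrow(k) - 1L) %/% 2L
  if (is.null(pad)) pad <- conv2d_pad(dim(x), kr)
  xp <- matrix(0, pad[1L], pad[2L])
  xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  if (is.null(k_fft)) k_fft <- conv2d_kernel_fft(k, pad)
  full <- Re(stats::fft(stats::fft(xp) * k_fft, inverse = TRUE)) /
    prod(pad)
  full[kr + seq_len(nrow(x)), kr + seq_len(ncol(x)), drop = FALSE]
}

conv2d_pad <- function(dim_x, kr) {
  c(stats::nextn(dim_x[1L] + 2L * kr, c(2, 3)),
    stats::nextn(dim_x[2L] + 2L * kr, c(2, 3)))
}

conv2d_kernel_fft <- function(k, pad) {
  kp <- matrix(0, pad[1L], pad[2L])
  kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  stats::fft(kp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
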
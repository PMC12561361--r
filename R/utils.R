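# Shared small helpers.

#' Coerce a sequence to a numeric matrix (samples x dimensions)
#'
#' Vectors become single-column matrices; matrices and data frames pass
#' through. Used by all alignment functions so 1-D and 2-D series share one
#' code path.
#'
#' @param x numeric vector, matrix, data frame, or [kinematic_series()].
#' @param arg name used in error messages.
#' @return numeric matrix with one row per time sample.
#' @keywords internal
as_seq_matrix <- function(x, arg = "x") {
  if (inherits(x, "kinematic_series")) x <- velocity_matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", arg))
  if (nrow(x) < 1L) stop(sprintf("'%s' must contain at least one sample", arg))
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", arg))
  x
}

check_same_dim <- function(y, z) {
  if (ncol(y) != ncol(z))
    stop(sprintf("dimensionality mismatch: %d vs %d", ncol(y), ncol(z)))
}

#' Z-score a multivariate series per dimension
#'
#' Each column is centred and scaled to unit standard deviation.
#' Zero-variance columns map to zeros rather than NaN, so constant
#' dimensions (e.g. a flat pen-lift axis) stay well defined.
#'
#' @param x numeric matrix or vector (samples x dimensions), or a
#'   [kinematic_series()] whose velocity is normalized.
#' @return object of the same shape with columns standardized.
#' @examples
#' zscore_per_dim(cbind(1:10, rep(2, 10)))
#' @export
zscore_per_dim <- function(x) {
  if (inherits(x, "kinematic_series")) {
    v <- zscore_per_dim(velocity_matrix(x))
    return(kinematic_series(v, fs = x$fs, origin = c(0, 0)))
  }
  vec <- is.null(dim(x))
  m <- as_seq_matrix(x)
  out <- apply(m, 2L, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(rep(0, length(col)))
    (col - mean(col)) / s
  })
  out <- matrix(out, nrow = nrow(m))
  if (vec) drop(out) else out
}

# Gradient of the per-dimension z-score transform: given upstream gradient g
# (same shape as x), returns dL/dx where u = (x - mean)/sd (sd with n-1
# denominator). Needed when a loss is computed on z-scored decoder output.
zscore_backprop <- function(x, g) {
  x <- as.matrix(x); g <- as.matrix(g)
  n <- nrow(x)
  out <- x * 0
  for (k in seq_len(ncol(x))) {
    s <- stats::sd(x[, k])
    if (!is.finite(s) || s == 0) next
    u <- (x[, k] - mean(x[, k])) / s
    gk <- g[, k]
    out[, k] <- (gk - mean(gk) - u * sum(gk * u) / (n - 1)) / s
  }
  out
}

# Deterministic per-task seed derived from a master seed (kept < 2^31).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Linear resampling of a series (matrix, rows = samples) to a new length.
resample_linear <- function(x, n_out) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1L) return(x[rep(1L, n_out), , drop = FALSE])
  t_in <- seq(0, 1, length.out = n)
  t_out <- seq(0, 1, length.out = n_out)
  apply(x, 2L, function(col) stats::approx(t_in, col, xout = t_out)$y)
}
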
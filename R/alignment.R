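# Exact and differentiable sequence alignment: DTW, fastDTW, soft-DTW,
# relaxed optimal paths, soft-TDI and the DILATE loss.

#' Pairwise squared-Euclidean cost matrix
#'
#' Computes the point-to-point loss matrix \eqn{\Delta(y, z)} with
#' \eqn{\Delta_{ij} = \lVert y_i - z_j \rVert^2}, the elementary cost used by
#' every alignment routine in the package.
#'
#' @param y,z numeric vectors or matrices (rows = time samples, columns =
#'   dimensions). Both must have the same dimensionality.
#' @return an \eqn{m \times n} matrix of nonnegative squared distances.
#' @examples
#' pairwise_cost(c(0, 1), 0.5)
#' @export
pairwise_cost <- function(y, z) {
  y <- as_seq_matrix(y, "y"); z <- as_seq_matrix(z, "z")
  check_same_dim(y, z)
  cpp_pairwise_cost(y, z)
}

#' Dynamic time warping distance and optimal alignment path
#'
#' Minimum cumulative squared-Euclidean cost over all monotone alignment
#' paths from (1,1) to (m,n), computed by dynamic programming; the optimal
#' path is recovered by backtracking (ties broken diagonal first, then
#' vertical, then horizontal, so results are deterministic).
#'
#' @inheritParams pairwise_cost
#' @return list with `distance` (nonnegative scalar) and `path`, a k x 2
#'   integer matrix of 1-based (i, j) index pairs starting at (1,1) and
#'   ending at (m,n).
#' @examples
#' dtw(c(0, 1, 2), c(0, 1, 1, 2))
#' @seealso [fast_dtw()], [soft_dtw()], [normalized_dtw()]
#' @export
dtw <- function(y, z) {
  delta <- pairwise_cost(y, z)
  cpp_dtw(delta)
}

#' Approximate DTW by coarse-to-fine search (fastDTW)
#'
#' Recursively halves both sequences, aligns the coarse pair, and refines the
#' projected path within a window of the given radius. The restricted search
#' guarantees `fast_dtw(y, z, r) >= dtw(y, z)`, with equality on smooth
#' sequences at modest radii.
#'
#' @inheritParams pairwise_cost
#' @param radius window radius (cells) around the projected coarse path.
#' @return as [dtw()].
#' @export
fast_dtw <- function(y, z, radius = 1L) {
  y <- as_seq_matrix(y, "y"); z <- as_seq_matrix(z, "z")
  check_same_dim(y, z)
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1")
  fast_dtw_rec(y, z, radius)
}

fast_dtw_rec <- function(y, z, radius) {
  m <- nrow(y); n <- nrow(z)
  if (min(m, n) <= radius + 2L) return(cpp_dtw(cpp_pairwise_cost(y, z)))
  ys <- halve_sequence(y)
  zs <- halve_sequence(z)
  coarse <- fast_dtw_rec(ys, zs, radius)
  allowed <- expand_window(coarse$path, m, n, radius)
  cpp_dtw(cpp_pairwise_cost(y, z), allowed)
}

halve_sequence <- function(x) {
  n <- nrow(x)
  k <- n %/% 2L
  idx1 <- 2L * seq_len(k) - 1L
  half <- (x[idx1, , drop = FALSE] + x[idx1 + 1L, , drop = FALSE]) / 2
  if (n %% 2L == 1L) half <- rbind(half, x[n, , drop = FALSE])
  half
}

expand_window <- function(coarse_path, m, n, radius) {
  allowed <- matrix(FALSE, m, n)
  for (k in seq_len(nrow(coarse_path))) {
    i <- coarse_path[k, 1L]; j <- coarse_path[k, 2L]
    ii <- max(1L, 2L * i - 1L - radius):min(m, 2L * i + radius)
    jj <- max(1L, 2L * j - 1L - radius):min(n, 2L * j + radius)
    allowed[ii, jj] <- TRUE
  }
  allowed[1L, 1L] <- TRUE
  allowed[m, n] <- TRUE
  allowed
}

#' Soft minimum (log-sum-exp relaxation of min)
#'
#' \eqn{\mathrm{softmin}_\gamma(a_1,\dots,a_n) = -\gamma \log \sum_i
#' \exp(-a_i/\gamma)}, evaluated with a max-shift so large cost/small
#' \eqn{\gamma} combinations neither overflow nor underflow. Always bounded
#' above by `min(values)` and converges to it as \eqn{\gamma \to 0^+}.
#'
#' @param values numeric vector (non-empty).
#' @param gamma smoothing temperature, > 0.
#' @return scalar soft minimum.
#' @examples
#' soft_min(c(0, 1), gamma = 1)  # -log(1 + exp(-1))
#' @export
soft_min <- function(values, gamma) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  mn <- min(values)
  if (!is.finite(mn)) return(mn)
  mn - gamma * log(sum(exp(-(values - mn) / gamma)))
}

#' Soft-DTW divergence
#'
#' Differentiable relaxation of DTW: the soft minimum, at temperature
#' `gamma`, of the cumulative cost over all admissible alignment paths,
#' computed by the soft-min dynamic program.
#'
#' @inheritParams pairwise_cost
#' @param gamma smoothing temperature, > 0.
#' @return scalar value (always `<= dtw(y, z)$distance`).
#' @export
soft_dtw <- function(y, z, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  delta <- pairwise_cost(y, z)
  cpp_softdtw(delta, gamma)$value
}

#' Relaxed optimal alignment path
#'
#' The gradient of soft-DTW with respect to the cost matrix: the expected
#' alignment matrix under the Gibbs distribution over admissible paths.
#' Entries lie in \[0, 1\] and both corner cells equal 1 (every path contains
#' them). As \eqn{\gamma \to 0^+} it concentrates on the hard DTW path.
#'
#' @inheritParams soft_dtw
#' @return m x n numeric matrix of expected path occupancies, with
#'   attribute `gamma`.
#' @export
relaxed_path <- function(y, z, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  delta <- pairwise_cost(y, z)
  fw <- cpp_softdtw(delta, gamma)
  E <- cpp_softdtw_grad(delta, fw$R, gamma)
  attr(E, "gamma") <- gamma
  E
}

# Time-penalty matrix Omega(i, j) = (i - j)^2, optionally divided by m*n so
# the time term stays on a scale comparable with the shape term.
omega_matrix <- function(m, n, normalize = TRUE) {
  om <- outer(seq_len(m), seq_len(n), function(i, j) (i - j)^2)
  if (normalize) om <- om / (m * n)
  om
}

#' Soft temporal distortion index (soft-TDI)
#'
#' Penalizes timing distortion: the inner product of the relaxed optimal
#' path with \eqn{\Omega(i,j) = (i-j)^2}, which grows as the expected
#' alignment deviates from the diagonal (one-to-one timing).
#'
#' @inheritParams soft_dtw
#' @param normalize divide \eqn{\Omega} by \eqn{m \cdot n} (default) so the
#'   penalty is invariant to sequence length.
#' @return nonnegative scalar.
#' @export
soft_tdi <- function(y, z, gamma, normalize = TRUE) {
  E <- relaxed_path(y, z, gamma)
  sum(E * omega_matrix(nrow(E), ncol(E), normalize))
}

#' DILATE shape-plus-time distortion loss
#'
#' Weighted sum of a shape term (soft-DTW) and a time term (soft-TDI):
#' \deqn{\mathrm{DILATE}_{\alpha,\gamma}(y, z) =
#'   \alpha\,\mathrm{softDTW}_\gamma(y,z) +
#'   (1-\alpha)\,\mathrm{softTDI}_\gamma(y,z).}
#' Differentiable end-to-end, so it can train trajectory decoders whose
#' labels are temporally misaligned with the neural signal.
#'
#' @inheritParams soft_tdi
#' @param alpha shape/time tradeoff in \[0, 1\]; `alpha = 1` is pure
#'   soft-DTW, `alpha = 0` pure soft-TDI. Default 0.5.
#' @param gamma smoothing temperature, > 0. Default 0.001.
#' @return scalar loss value.
#' @seealso [dilate_grad()] for the value together with its gradient.
#' @export
dilate_loss <- function(y, z, alpha = 0.5, gamma = 0.001, normalize = TRUE) {
  dilate_grad(y, z, alpha = alpha, gamma = gamma, normalize = normalize,
              want_grad = FALSE)$loss
}

#' DILATE loss with analytic gradient
#'
#' Evaluates the DILATE loss and (optionally) its gradient with respect to
#' the prediction `z`. The shape-term gradient is the relaxed path chained
#' through the squared-Euclidean costs; the time-term gradient treats
#' \eqn{\Omega} as constant and differentiates the Gibbs path weights via a
#' Hessian-vector product of soft-DTW.
#'
#' @inheritParams dilate_loss
#' @param want_grad compute the gradient (default `TRUE`).
#' @return list with `loss`, `shape`, `time`, `path` (the relaxed path) and,
#'   when requested, `grad` (same shape as `z`).
#' @export
dilate_grad <- function(y, z, alpha = 0.5, gamma = 0.001, normalize = TRUE,
                        want_grad = TRUE) {
  y <- as_seq_matrix(y, "y"); z <- as_seq_matrix(z, "z")
  check_same_dim(y, z)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]")
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  cpp_dilate(y, z, alpha, gamma, normalize, want_grad)
}

#' Warp a predicted sequence onto the reference timeline
#'
#' Computes the hard DTW path between `reference` and `predicted` and maps
#' each reference index i to the first predicted index aligned with it
#' (`index_i = min{j : A[i,j] = 1}`), returning
#' `predicted[index_1], ..., predicted[index_m]`.
#'
#' @param reference,predicted numeric vectors/matrices or
#'   [kinematic_series()] objects of equal dimensionality.
#' @return matrix (or vector for 1-D input) with `nrow(reference)` samples.
#' @export
warp_to_reference <- function(reference, predicted) {
  vec <- is.null(dim(predicted)) && !inherits(predicted, "kinematic_series")
  ref <- as_seq_matrix(reference, "reference")
  prd <- as_seq_matrix(predicted, "predicted")
  check_same_dim(ref, prd)
  path <- dtw(ref, prd)$path
  idx <- vapply(seq_len(nrow(ref)),
                function(i) min(path[path[, 1L] == i, 2L]), integer(1L))
  out <- prd[idx, , drop = FALSE]
  if (vec) drop(out) else out
}

#' Alignment-offset statistics between a label and a decoded series
#'
#' Runs hard DTW between the label and decoded kinematics, reads off the
#' per-point alignment offset `(i - index_i) * bin_ms` along the optimal
#' path, and summarizes it: the signed mean, the mean of absolute offsets,
#' and the within-trial standard deviation of absolute offsets.
#'
#' @param label,decoded kinematic series (vectors, matrices, or
#'   [kinematic_series()]).
#' @param bin_ms kinematic bin width in milliseconds (default 50, i.e.
#'   20 Hz).
#' @return object of class `offset_stats`: list with `per_point_offsets`
#'   (signed, ms), `mean_ms`, `mean_abs_ms`, `sd_ms`.
#' @export
alignment_offsets <- function(label, decoded, bin_ms = 50) {
  lab <- as_seq_matrix(label, "label")
  dec <- as_seq_matrix(decoded, "decoded")
  check_same_dim(lab, dec)
  path <- dtw(lab, dec)$path
  idx <- vapply(seq_len(nrow(lab)),
                function(i) min(path[path[, 1L] == i, 2L]), integer(1L))
  off <- (seq_len(nrow(lab)) - idx) * bin_ms
  structure(list(per_point_offsets = off,
                 mean_ms = mean(off),
                 mean_abs_ms = mean(abs(off)),
                 sd_ms = stats::sd(abs(off))),
            class = "offset_stats")
}

#' @export
print.offset_stats <- function(x, ...) {
  cat(sprintf(
    "Alignment offsets: %d points, mean %.2f ms (|mean| %.2f ms), SD(|offset|) %.2f ms\n",
    length(x$per_point_offsets), x$mean_ms, x$mean_abs_ms, x$sd_ms))
  invisible(x)
}

#' Normalized DTW distance
#'
#' Standard DTW distance divided by the length (cell count) of the optimal
#' warping path; lower values indicate a better trajectory reconstruction.
#'
#' @inheritParams pairwise_cost
#' @return nonnegative scalar.
#' @export
normalized_dtw <- function(y, z) {
  a <- dtw(y, z)
  a$distance / nrow(a$path)
}

#' Export an alignment path as a data frame
#'
#' @param path k x 2 integer matrix as returned in `dtw(...)$path`.
#' @param file optional path; when given the index pairs are written as CSV.
#' @return data frame with columns `i`, `j` (invisibly when written).
#' @export
alignment_path_df <- function(path, file = NULL) {
  df <- data.frame(i = path[, 1L], j = path[, 2L])
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
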
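# Linear Kalman-filter trajectory decoder.

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

as_state_matrix <- function(x) {
  if (inherits(x, "kinematic_series")) x <- velocity_matrix(x)
  as.matrix(x)
}

#' Fit a velocity Kalman filter to paired kinematic/neural trials
#'
#' State is the 2-D velocity augmented with a constant-1 bias channel. The
#' state-transition matrix `A` and observation matrix `H` are estimated by
#' least squares over all stacked training pairs; `Q` and `R` are the
#' corresponding residual covariances; the control input `B` is fixed at 0.
#' Rank-deficient regressors fall back to a small ridge with a warning.
#'
#' @param states list of velocity trials (n x 2 matrices or
#'   [kinematic_series()]).
#' @param observations list of matching feature trials ([feature_matrix()]
#'   or bins x channels matrices), equal lengths per trial.
#' @return object of class `kalman_decoder` with elements `A`, `H`, `Q`,
#'   `R` (and `state_dim`, `obs_dim`).
#' @export
fit_kalman <- function(states, observations) {
  stopifnot(length(states) == length(observations))
  xs <- lapply(states, function(s) cbind(as_state_matrix(s), 1))
  zs <- lapply(observations, timebins)
  for (k in seq_along(xs))
    if (nrow(xs[[k]]) != nrow(zs[[k]]))
      stop("state/observation length mismatch in trial ", k)
  X_now <- do.call(rbind, lapply(xs, function(x) x[-nrow(x), , drop = FALSE]))
  X_next <- do.call(rbind, lapply(xs, function(x) x[-1L, , drop = FALSE]))
  X_all <- do.call(rbind, xs)
  Z_all <- do.call(rbind, zs)

  lsq <- function(X, Y) {  # coefficients of Y ~ X, rows of result map X -> Y
    G <- crossprod(X)
    if (rcond(G) < 1e-12) {
      warning("rank-deficient regressors; using ridge fallback")
      G <- G + diag(1e-8 * max(diag(G)), ncol(G))
    }
    t(solve(G, crossprod(X, Y)))
  }

  A_vel <- lsq(X_now, X_next[, 1:2, drop = FALSE])   # 2 x 3
  A <- rbind(A_vel, c(0, 0, 1))
  resA <- X_next - X_now %*% t(A)
  Q <- crossprod(resA) / max(1L, nrow(resA) - 1L)
  H <- lsq(X_all, Z_all)                             # C x 3
  resH <- Z_all - X_all %*% t(H)
  R <- crossprod(resH) / max(1L, nrow(resH) - 1L)
  structure(list(A = A, H = H, Q = Q, R = R,
                 state_dim = 3L, obs_dim = ncol(Z_all)),
            class = "kalman_decoder")
}

#' @export
print.kalman_decoder <- function(x, ...) {
  cat(sprintf("Kalman trajectory decoder: %d-dim state (velocity + bias), %d observation channels\n",
              x$state_dim, x$obs_dim))
  invisible(x)
}

#' @export
coef.kalman_decoder <- function(object, ...) {
  object[c("A", "H", "Q", "R")]
}

#' Run the Kalman filter over a trial of observations
#'
#' Recursive predict/update: state prediction and covariance propagation,
#' gain computation, then measurement update, starting from a zero velocity
#' state with covariance `Q`. A singular innovation covariance falls back
#' to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param model a fitted [fit_kalman()] decoder (or a list with `A`, `H`,
#'   `Q`, `R`, for hand-specified systems).
#' @param observations one trial ([feature_matrix()] or bins x channels
#'   matrix).
#' @param x0,P0 optional initial state and covariance (defaults: zero
#'   velocity with bias 1, `P0 = I`).
#' @return bins x state-dim matrix of filtered state estimates.
#' @export
kalman_decode <- function(model, observations, x0 = NULL, P0 = NULL) {
  Z <- timebins(observations)
  A <- model$A; H <- model$H; Q <- model$Q; R <- model$R
  d <- nrow(A)
  if (is.null(x0))
    x0 <- if (d >= 3L) c(rep(0, d - 1L), 1) else rep(0, d)
  if (length(x0) != d) x0 <- rep(x0, length.out = d)
  if (is.null(P0)) P0 <- diag(d)
  x <- x0; P <- P0
  out <- matrix(NA_real_, nrow(Z), d)
  I <- diag(d)
  for (t in seq_len(nrow(Z))) {
    xp <- A %*% x                       # state prediction (B u = 0)
    Pp <- A %*% P %*% t(A) + Q          # covariance prediction
    S <- H %*% Pp %*% t(H) + R          # innovation covariance
    Sinv <- tryCatch(solve(S), error = function(e) {
      warning("singular innovation covariance; using pseudo-inverse")
      pinv(S)
    })
    K <- Pp %*% t(H) %*% Sinv           # gain
    x <- xp + K %*% (Z[t, ] - H %*% xp) # update
    P <- (I - K %*% H) %*% Pp
    out[t, ] <- x
  }
  out
}

#' @export
predict.kalman_decoder <- function(object, observations, ...) {
  kalman_decode(object, observations)[, 1:2, drop = FALSE]
}
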
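# Gradient-trained trajectory decoders: LSTM sequence decoder and the
# single-layer linear decoder used in the simulation experiments, both
# trainable under MSE or DILATE.

#' Loss specification for decoder training
#'
#' @param kind `"mse"` or `"dilate"`.
#' @param alpha,gamma,normalize DILATE parameters (defaults 0.5, 0.001,
#'   normalized time penalty).
#' @param zscore z-score decoder output and label per dimension before the
#'   DILATE loss (the convention for neural fitting, where the initial
#'   output scale is arbitrary); ignored for MSE.
#' @return list of class `loss_spec`.
#' @export
loss_spec <- function(kind = c("mse", "dilate"), alpha = 0.5, gamma = 0.001,
                      normalize = TRUE, zscore = TRUE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, alpha = alpha, gamma = gamma,
                 normalize = normalize, zscore = zscore),
            class = "loss_spec")
}

#' Training configuration
#'
#' @param epochs maximum training epochs (default 100).
#' @param lr learning rate (default 0.001).
#' @param hidden LSTM hidden units (default 512).
#' @param seed master seed; per-epoch shuffles and initialisation derive
#'   from it.
#' @param noise_scale feature noise-augmentation scale (0 disables).
#' @param patience early-stop patience: training stops when the smoothed
#'   epoch loss has not improved for this many epochs (default 10).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 0.001, hidden = 512L, seed = 1L,
                         noise_scale = 0, patience = 10L) {
  if (epochs < 1L) stop("'epochs' must be positive")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 hidden = as.integer(hidden), seed = as.integer(seed),
                 noise_scale = noise_scale, patience = as.integer(patience)),
            class = "train_config")
}

# ---- loss evaluation: value + gradient w.r.t. the prediction ----------------

loss_value_grad <- function(pred, target, loss) {
  if (loss$kind == "mse") {
    d <- pred - target
    list(value = mean(d^2), grad = 2 * d / length(d))
  } else {
    if (loss$zscore) {
      pz <- zscore_per_dim(pred)
      tz <- zscore_per_dim(target)
      res <- dilate_grad(tz, pz, alpha = loss$alpha, gamma = loss$gamma,
                         normalize = loss$normalize)
      list(value = res$loss, grad = zscore_backprop(pred, res$grad))
    } else {
      res <- dilate_grad(target, pred, alpha = loss$alpha, gamma = loss$gamma,
                         normalize = loss$normalize)
      list(value = res$loss, grad = res$grad)
    }
  }
}

# ---- Adam optimizer state ---------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- LSTM core --------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

lstm_init <- function(d_in, hidden, d_out, seed) {
  with_seed(derive_seed(seed, "init"), {
    gl <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) *
                                    sqrt(6 / (nr + nc)), nr, nc)
    b <- rep(0, 4L * hidden)
    b[hidden + seq_len(hidden)] <- 1  # forget-gate bias
    list(W = gl(4L * hidden, d_in), U = gl(4L * hidden, hidden), b = b,
         Wy = gl(d_out, hidden), by = rep(0, d_out))
  })
}

# Forward pass; returns predictions and the caches needed by BPTT.
lstm_forward <- function(params, X) {
  Tn <- nrow(X); h <- length(params$by) * 0 # placeholder
  H <- ncol(params$U)
  hs <- matrix(0, Tn, H); cs <- matrix(0, Tn, H)
  gi <- matrix(0, Tn, H); gf <- matrix(0, Tn, H)
  go <- matrix(0, Tn, H); gg <- matrix(0, Tn, H)
  h_prev <- rep(0, H); c_prev <- rep(0, H)
  WX <- X %*% t(params$W)  # Tn x 4H
  for (t in seq_len(Tn)) {
    z <- WX[t, ] + as.numeric(params$U %*% h_prev) + params$b
    i <- sigmoid(z[seq_len(H)])
    f <- sigmoid(z[H + seq_len(H)])
    o <- sigmoid(z[2L * H + seq_len(H)])
    g <- tanh(z[3L * H + seq_len(H)])
    c_t <- f * c_prev + i * g
    h_t <- o * tanh(c_t)
    gi[t, ] <- i; gf[t, ] <- f; go[t, ] <- o; gg[t, ] <- g
    cs[t, ] <- c_t; hs[t, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  E <- elu(hs)
  Y <- E %*% t(params$Wy) + matrix(params$by, Tn, length(params$by), byrow = TRUE)
  list(Y = Y, hs = hs, cs = cs, gi = gi, gf = gf, go = go, gg = gg, E = E)
}

lstm_backward <- function(params, X, fw, dY) {
  Tn <- nrow(X); H <- ncol(params$U)
  dWy <- t(dY) %*% fw$E
  dby <- colSums(dY)
  dE <- dY %*% params$Wy
  dH_out <- dE * elu_grad(fw$hs)
  dW <- params$W * 0; dU <- params$U * 0; db <- params$b * 0
  dh_next <- rep(0, H); dc_next <- rep(0, H)
  for (t in rev(seq_len(Tn))) {
    dh <- dH_out[t, ] + dh_next
    c_t <- fw$cs[t, ]; tc <- tanh(c_t)
    o <- fw$go[t, ]; i <- fw$gi[t, ]; f <- fw$gf[t, ]; g <- fw$gg[t, ]
    c_prev <- if (t > 1L) fw$cs[t - 1L, ] else rep(0, H)
    h_prev <- if (t > 1L) fw$hs[t - 1L, ] else rep(0, H)
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g; dg <- dc * i; df <- dc * c_prev
    dc_next <- dc * f
    dz <- c(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
            dg * (1 - g^2))
    dW <- dW + outer(dz, X[t, ])
    dU <- dU + outer(dz, h_prev)
    db <- db + dz
    dh_next <- as.numeric(t(params$U) %*% dz)
  }
  list(W = dW, U = dU, b = db, Wy = dWy, by = dby)
}

# ---- shared training loop ---------------------------------------------------

run_training <- function(params, trials_X, trials_Y, loss, cfg,
                         forward, backward) {
  opt <- adam_new(params)
  history <- numeric(0)
  best <- Inf; best_params <- params; stale <- 0L
  lr <- cfg$lr
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "shuffle", ep),
                     sample(length(trials_X)))
    ep_loss <- 0
    for (k in ord) {
      X <- trials_X[[k]]
      if (cfg$noise_scale > 0)
        X <- augment_noise(X, cfg$noise_scale,
                           seed = derive_seed(cfg$seed, "aug", ep, k))
      fw <- forward(params, X)
      lv <- loss_value_grad(fw$Y, trials_Y[[k]], loss)
      if (!is.finite(lv$value))
        stop(sprintf("non-finite training loss at epoch %d, trial %d", ep, k))
      grads <- backward(params, X, fw, lv$grad)
      step <- adam_step(params, grads, opt, lr)
      params <- step$params; opt <- step$state
      ep_loss <- ep_loss + lv$value
    }
    history[ep] <- ep_loss / length(trials_X)
    if (history[ep] < best - 1e-10) {
      best <- history[ep]; best_params <- params; stale <- 0L
    } else {
      stale <- stale + 1L
      # halve the step on a sustained plateau; per-trial updates under the
      # near-hard soft-min are noisy, so the schedule matters more than the
      # base rate
      if (stale %% max(2L, cfg$patience %/% 2L) == 0L) lr <- lr / 2
    }
    if (stale >= cfg$patience) break
  }
  list(params = best_params, history = history)
}

#' Train the LSTM sequence decoder
#'
#' A single-layer LSTM followed by an exponential-linear activation and an
#' affine readout to 2-D velocity, trained trial-by-trial (batch size 1)
#' with adaptive-moment gradient descent. Under the DILATE loss the output
#' and label are z-scored per dimension before the loss and the analytic
#' DILATE gradient is backpropagated through time.
#'
#' @param features list of trials ([feature_matrix()] or bins x channels).
#' @param targets list of matching velocity targets (n x 2 or
#'   [kinematic_series()]).
#' @param loss a [loss_spec()].
#' @param cfg a [train_config()].
#' @return object of class `seq_decoder` with the parameters, configs and
#'   per-epoch `history` of the training loss.
#' @export
train_decoder <- function(features, targets, loss = loss_spec(),
                          cfg = train_config()) {
  stopifnot(length(features) == length(targets))
  Xs <- lapply(features, timebins)
  Ys <- lapply(targets, as_state_matrix)
  for (k in seq_along(Xs))
    if (nrow(Xs[[k]]) != nrow(Ys[[k]]))
      stop("feature/target length mismatch in trial ", k)
  d_in <- ncol(Xs[[1L]]); d_out <- ncol(Ys[[1L]])
  params <- lstm_init(d_in, cfg$hidden, d_out, cfg$seed)
  fit <- run_training(params, Xs, Ys, loss, cfg, lstm_forward, lstm_backward)
  structure(list(params = fit$params, history = fit$history, loss = loss,
                 cfg = cfg, d_in = d_in, d_out = d_out,
                 architecture = "lstm"),
            class = "seq_decoder")
}

#' Train the single-layer linear decoder
#'
#' The decoder used in the simulation experiments: one linear layer from
#' feature channels to 2-D velocity, trained per trial with
#' adaptive-moment gradient descent under MSE or DILATE. The simulation
#' convention applies DILATE to raw (not z-scored) velocities, so the
#' default `loss_spec` is overridden accordingly by the callers that need
#' it.
#'
#' @inheritParams train_decoder
#' @return object of class `seq_decoder` with `architecture = "linear"`.
#' @export
train_linear_decoder <- function(features, targets,
                                 loss = loss_spec(), cfg = train_config()) {
  stopifnot(length(features) == length(targets))
  Xs <- lapply(features, timebins)
  Ys <- lapply(targets, as_state_matrix)
  d_in <- ncol(Xs[[1L]]); d_out <- ncol(Ys[[1L]])
  params <- with_seed(derive_seed(cfg$seed, "init"),
                      list(W = matrix(stats::rnorm(d_in * d_out, 0, 0.01),
                                      d_in, d_out),
                           b = rep(0, d_out)))
  forward <- function(p, X)
    list(Y = X %*% p$W + matrix(p$b, nrow(X), d_out, byrow = TRUE))
  backward <- function(p, X, fw, dY)
    list(W = t(X) %*% dY, b = colSums(dY))
  fit <- run_training(params, Xs, Ys, loss, cfg, forward, backward)
  structure(list(params = fit$params, history = fit$history, loss = loss,
                 cfg = cfg, d_in = d_in, d_out = d_out,
                 architecture = "linear"),
            class = "seq_decoder")
}

#' @export
print.seq_decoder <- function(x, ...) {
  cat(sprintf("%s decoder: %d -> %d, loss %s, trained %d epochs (final loss %.4g)\n",
              toupper(x$architecture), x$d_in, x$d_out, x$loss$kind,
              length(x$history), utils::tail(x$history, 1L)))
  invisible(x)
}

#' @export
plot.seq_decoder <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = sprintf("%s / %s", x$architecture, x$loss$kind), ...)
  invisible(x)
}

#' @export
predict.seq_decoder <- function(object, features, ...) {
  X <- timebins(features)
  if (object$architecture == "lstm") lstm_forward(object$params, X)$Y
  else X %*% object$params$W +
    matrix(object$params$b, nrow(X), object$d_out, byrow = TRUE)
}

#' Decode a feature trial into kinematics
#'
#' Runs a fitted decoder over one trial of features and wraps the predicted
#' velocity as a [kinematic_series()] (position obtained by integration).
#'
#' @param model a `seq_decoder` or `kalman_decoder`.
#' @param features one trial ([feature_matrix()] or bins x channels).
#' @param fs kinematic sampling rate (default 20 Hz).
#' @return a [kinematic_series()].
#' @export
decode <- function(model, features, fs = 20) {
  v <- predict(model, features)
  kinematic_series(v[, 1:2, drop = FALSE], fs = fs)
}
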
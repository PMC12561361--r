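# Simulation experiments: timeline-resampling misalignment, the 1-D
# delayed-copy loss landscape, and multi-day data fusion.

#' Randomly resample a trajectory's timeline (shape-preserving)
#'
#' Draws as many time points as the trajectory has samples uniformly over
#' its time range, sorts them (the final point is clamped to the end of the
#' range so the endpoint is preserved), reads positions off the space-time
#' polyline by linear interpolation (uniform velocity between samples), and
#' differentiates to obtain the misaligned "actual" velocity. The resampled
#' positions lie exactly on the original path: the written shape is
#' unchanged, only the timing is distorted.
#'
#' @param P n x 2 position matrix (uniform time grid) or a
#'   [kinematic_series()].
#' @param origin position at time 0 (before the first sample); taken from
#'   the series when available.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param times optional explicit sorted time draw (sample units in
#'   `[0, n]`), overriding the random draw; the identity grid `1:n`
#'   reproduces the input exactly.
#' @return list with `P` (resampled positions), `V` (finite-difference
#'   velocity, n x 2) and `times`.
#' @export
resample_timeline <- function(P, origin = NULL, fs = 20, seed = 1L,
                              times = NULL) {
  if (inherits(P, "kinematic_series")) {
    origin <- P$origin; fs <- P$fs
    P <- cbind(P$x, P$y)
  }
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 2L) stop("trajectory needs at least 2 samples")
  if (is.null(origin)) origin <- P[1L, ]
  if (is.null(times)) {
    times <- with_seed(derive_seed(seed, "resample"), sort(stats::runif(n, 0, n)))
    times[n] <- n  # preserve the endpoint of the time range
  } else {
    if (length(times) != n || is.unsorted(times)) stop("'times' must be sorted, length n")
  }
  grid <- 0:n
  path <- rbind(origin, P)
  Pp <- vapply(1:2, function(d) stats::approx(grid, path[, d], xout = times)$y,
               numeric(n))
  Pp <- matrix(Pp, n, 2L)
  V <- rbind(Pp[1L, ] - origin, diff(Pp)) * fs
  list(P = Pp, V = V, times = times)
}

#' Encode velocity into simulated neural features
#'
#' The fixed linear encoder of the simulation experiments:
#' `S = V %*% t(W) + b`.
#'
#' @param V n x 2 velocity matrix.
#' @param encoder from [make_linear_encoder()].
#' @return n x channels matrix.
#' @export
linear_encode <- function(V, encoder) {
  V <- as.matrix(V)
  sweep(V %*% t(encoder$W), 2L, encoder$b, "+")
}

cc_metric <- function(a, b) stats::cor(as.vector(a), as.vector(b))
mse_metric <- function(a, b) mean((a - b)^2)

make_folds <- function(ids, folds, seed) {
  ids <- sort(unique(ids))
  ord <- with_seed(derive_seed(seed, "folds"), sample(ids))
  split(ord, rep_len(seq_len(folds), length(ord)))
}

sim_loss_spec <- function(kind) {
  # simulation convention: DILATE on raw velocities (no z-scoring)
  loss_spec(kind, zscore = FALSE)
}

#' Misalignment simulation: DILATE versus MSE under timeline resampling
#'
#' Full pipeline of the misalignment experiment: synthesize prompted
#' kinematics for every glyph, resample each trial's timeline (the
#' subject's actual velocity), encode the actual velocity through a fixed
#' linear encoder with observation noise, train a linear decoder per loss
#' under character-level k-fold cross-validation with the prompted velocity
#' as target, and score the held-out predictions: correlation and MSE
#' against the actual velocity, plus the DTW template recognition rate of
#' the decoded trajectories.
#'
#' @param corpus glyph corpus (default [letter_corpus()]).
#' @param losses character vector among `"mse"`, `"dilate"`.
#' @param folds cross-validation folds at the character level (default 5).
#' @param seed master seed.
#' @param repetitions repetitions (independent resamplings) per glyph.
#' @param misalign apply timeline resampling (default `TRUE`); `FALSE`
#'   gives the aligned control condition.
#' @param noise_sd observation-noise scale (see [simulate_session()]).
#' @param n_channels encoder channels (default 96).
#' @param epochs,lr training schedule for the linear decoder.
#' @return object of class `misalignment_experiment`: `summary` data frame
#'   (per loss: `cc`, `mse`, `recognition_rate`), `trials` (per-trial
#'   details), and the session objects.
#' @export
run_misalignment_experiment <- function(corpus = letter_corpus(),
                                        losses = c("mse", "dilate"),
                                        folds = 5L, seed = 1L,
                                        repetitions = 3L, misalign = TRUE,
                                        noise_sd = 1, n_channels = 96L,
                                        epochs = 150L, lr = 0.005) {
  encoder <- make_linear_encoder(n_channels, seed = seed)
  session <- simulate_session(corpus, encoder = encoder,
                              repetitions = repetitions, misalign = misalign,
                              noise_sd = noise_sd, seed = seed)
  library <- build_library(corpus)
  ids <- vapply(session$trials, `[[`, character(1L), "id")
  fold_sets <- make_folds(ids, folds, seed)
  rows <- list(); per_trial <- list()
  for (lk in losses) {
    preds <- vector("list", length(session$trials))
    for (f in seq_along(fold_sets)) {
      test_ids <- fold_sets[[f]]
      tr <- which(!ids %in% test_ids)
      te <- which(ids %in% test_ids)
      dec <- train_linear_decoder(
        lapply(session$trials[tr], `[[`, "features"),
        lapply(session$trials[tr], function(x) velocity_matrix(x$label)),
        loss = sim_loss_spec(lk),
        cfg = train_config(epochs = epochs, lr = lr, patience = 40L,
                           seed = derive_seed(seed, "train", lk, f)))
      for (k in te) preds[[k]] <- predict(dec, session$trials[[k]]$features)
    }
    stats_df <- do.call(rbind, lapply(seq_along(preds), function(k) {
      tr <- session$trials[[k]]
      rec <- recognize(preds[[k]], library, truth = tr$id)
      data.frame(loss = lk, id = tr$id, rep = tr$rep,
                 cc = cc_metric(preds[[k]], tr$v_actual),
                 mse = mse_metric(preds[[k]], tr$v_actual),
                 correct = rec$top1_correct,
                 ndtw = normalized_dtw(velocity_matrix(tr$label), preds[[k]]))
    }))
    per_trial[[lk]] <- stats_df
    rows[[lk]] <- data.frame(loss = lk, cc = mean(stats_df$cc),
                             mse = mean(stats_df$mse),
                             recognition_rate = mean(stats_df$correct),
                             ndtw = mean(stats_df$ndtw))
  }
  structure(list(summary = do.call(rbind, rows),
                 trials = do.call(rbind, per_trial),
                 session = session, misalign = misalign, seed = seed),
            class = "misalignment_experiment")
}

#' @export
print.misalignment_experiment <- function(x, ...) {
  cat(sprintf("Misalignment simulation (%s):\n",
              if (x$misalign) "timeline resampling on" else "aligned control"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Reference input for the 1-D delayed-copy loss landscape
#'
#' The label `y` is a flat baseline of 100 samples with a triangular speed
#' bump (values 10, 25, 30, 25, 10 at samples 31-35; mean 1), and `x` is
#' the same shape delayed by `delay` samples: an executed movement whose
#' timing lags the prompt while the shape is identical.
#'
#' @param delay delay in samples (default 8).
#' @return list with numeric vectors `y` and `x`.
#' @export
toy_reference_input <- function(delay = 8L) {
  y <- numeric(100L)
  y[31:35] <- c(10, 25, 30, 25, 10)
  x <- numeric(100L)
  x[31:35 + delay] <- c(10, 25, 30, 25, 10)
  list(y = y, x = x)
}

#' Loss landscape of a 1-D linear decoder on a delayed copy
#'
#' With a linear encoder and decoder the prediction is `a*x + b`; the
#' landscape evaluates each loss over a grid of `(a, b)` and locates its
#' minimum. With the delayed-bump reference input the MSE minimum sits at
#' the flat line `(a, b) = (0, 1)` while DILATE's sits at the identity
#' `(1, 0)`, i.e. DILATE prefers preserving the shape regardless of delay.
#' No z-scoring is applied inside the losses here (it would erase the
#' `(a, b)` dependence).
#'
#' @param y label sequence (default: the reference input's `y`).
#' @param x delayed-copy input (default: the reference input's `x`).
#' @param a_grid,b_grid grids for slope and intercept (defaults
#'   `seq(-2, 2, 0.1)` and `seq(-1, 2, 0.1)`); both must include 0 and 1.
#' @param losses subset of `c("mse", "dilate")`.
#' @param alpha,gamma,normalize DILATE parameters (0.5, 0.001, normalized).
#' @return object of class `loss_landscape`: `surfaces` (named list of
#'   `length(a_grid)` x `length(b_grid)` matrices), `argmin` (named list of
#'   `c(a, b)`), and the grids.
#' @export
toy_landscape <- function(y = NULL, x = NULL,
                          a_grid = seq(-2, 2, by = 0.1),
                          b_grid = seq(-1, 2, by = 0.1),
                          losses = c("mse", "dilate"),
                          alpha = 0.5, gamma = 0.001, normalize = TRUE) {
  if (is.null(y) || is.null(x)) {
    ref <- toy_reference_input()
    if (is.null(y)) y <- ref$y
    if (is.null(x)) x <- ref$x
  }
  for (g in list(a_grid, b_grid))
    if (min(abs(g)) > 1e-9 || min(abs(g - 1)) > 1e-9)
      stop("grids must include 0 and 1")
  ym <- matrix(y, ncol = 1L)
  surfaces <- lapply(losses, function(lk) {
    s <- matrix(NA_real_, length(a_grid), length(b_grid),
                dimnames = list(sprintf("a=%g", a_grid), sprintf("b=%g", b_grid)))
    for (ai in seq_along(a_grid))
      for (bi in seq_along(b_grid)) {
        pred <- a_grid[ai] * x + b_grid[bi]
        s[ai, bi] <- if (lk == "mse") mean((pred - y)^2)
        else dilate_loss(ym, matrix(pred, ncol = 1L),
                         alpha = alpha, gamma = gamma, normalize = normalize)
      }
    s
  })
  names(surfaces) <- losses
  argmin <- lapply(surfaces, function(s) {
    ij <- which(s == min(s), arr.ind = TRUE)[1L, ]
    c(a = a_grid[ij[1L]], b = b_grid[ij[2L]])
  })
  structure(list(surfaces = surfaces, argmin = argmin,
                 a_grid = a_grid, b_grid = b_grid),
            class = "loss_landscape")
}

#' @export
print.loss_landscape <- function(x, ...) {
  cat("Loss landscape minima over the (a, b) grid:\n")
  for (nm in names(x$argmin))
    cat(sprintf("  %-7s a = %g, b = %g\n", nm, x$argmin[[nm]]["a"],
                x$argmin[[nm]]["b"]))
  invisible(x)
}

#' @export
plot.loss_landscape <- function(x, which = names(x$surfaces)[1L], ...) {
  s <- x$surfaces[[which]]
  graphics::image(x$a_grid, x$b_grid, log10(s - min(s) + 1e-12),
                  xlab = "a (slope)", ylab = "b (intercept)",
                  main = sprintf("%s loss (log10)", which), ...)
  am <- x$argmin[[which]]
  graphics::points(am["a"], am["b"], pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Pool multi-day sessions with per-day channel normalization
#'
#' Z-scores every session's features per channel (that day's statistics),
#' then concatenates the trials. Also returns leave-one-character-out fold
#' assignments that hold out one character per day.
#'
#' @param day_sessions list of [simulate_session()] objects (or lists of
#'   trials).
#' @return list of class `fused_dataset`: `trials` (pooled, each tagged
#'   with `day`), `folds` (list of held-out id sets, one character per day
#'   per fold), `day_stats`.
#' @export
multiday_fuse <- function(day_sessions) {
  pooled <- list(); day_stats <- list(); per_day_ids <- list()
  for (d in seq_along(day_sessions)) {
    s <- day_sessions[[d]]
    trials <- if (inherits(s, "session")) s$trials else s
    feats <- do.call(rbind, lapply(trials, `[[`, "features"))
    mu <- colMeans(feats); sdv <- apply(feats, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- Inf
    day_stats[[d]] <- list(mean = mu, sd = sdv)
    for (tr in trials) {
      tr$features <- sweep(sweep(tr$features, 2L, mu, "-"), 2L, sdv, "/")
      tr$day <- d
      pooled[[length(pooled) + 1L]] <- tr
    }
    per_day_ids[[d]] <- sort(unique(vapply(trials, `[[`, character(1L), "id")))
  }
  n_folds <- min(lengths(per_day_ids))
  folds <- lapply(seq_len(n_folds), function(f)
    vapply(per_day_ids, `[[`, character(1L), f))
  structure(list(trials = pooled, folds = folds, day_stats = day_stats),
            class = "fused_dataset")
}

#' Multi-day fusion simulation: decoding performance versus days of data
#'
#' Extends the misalignment simulation across simulated days: day 1 uses
#' the given corpus, later days contribute new (random) characters, all
#' resampled per trial and passed through the same fixed encoder with
#' per-day gain/offset drift. For each evaluated day count D the decoder is
#' trained on day-1 training folds plus all trials of days 2..D (features
#' z-scored per day before pooling) and always tested on the held-out
#' day-1 folds, so the test set never changes.
#'
#' @inheritParams run_misalignment_experiment
#' @param n_days total simulated days (default 6).
#' @param days_eval day counts D at which to evaluate (default `1:n_days`).
#' @param min_updates minimum number of per-trial gradient updates per fold
#'   (default 12000); small training sets get proportionally more epochs so
#'   every day count receives a comparable optimization budget.
#' @return object of class `multiday_experiment`: `summary` data frame with
#'   `loss`, `days`, `cc`, `recognition_rate`.
#' @export
run_multiday_experiment <- function(corpus = letter_corpus(), n_days = 6L,
                                    days_eval = NULL,
                                    losses = c("mse", "dilate"),
                                    folds = 5L, seed = 1L, repetitions = 3L,
                                    noise_sd = 1, n_channels = 96L,
                                    epochs = 60L, lr = 0.005,
                                    min_updates = 12000L) {
  if (is.null(days_eval)) days_eval <- seq_len(n_days)
  encoder <- make_linear_encoder(n_channels, seed = seed)
  sessions <- vector("list", n_days)
  sessions[[1L]] <- simulate_session(corpus, encoder = encoder,
                                     repetitions = repetitions,
                                     misalign = TRUE, day = 1L,
                                     noise_sd = noise_sd, seed = seed)
  n_chars <- length(if (inherits(corpus, "glyph_corpus")) corpus$templates else corpus)
  for (d in seq_len(n_days)[-1L]) {
    glyphs <- lapply(seq_len(n_chars), function(k)
      random_glyph(derive_seed(seed, "dayglyph", d, k),
                   n_strokes = 1L + (k %% 4L)))
    sessions[[d]] <- simulate_session(glyphs, encoder = encoder,
                                      repetitions = repetitions,
                                      misalign = TRUE, day = d,
                                      noise_sd = noise_sd, seed = seed + d)
  }
  fused <- multiday_fuse(sessions)
  days <- vapply(fused$trials, `[[`, integer(1L), "day")
  ids <- vapply(fused$trials, `[[`, character(1L), "id")
  day1_ids <- sort(unique(ids[days == 1L]))
  fold_sets <- make_folds(ids[days == 1L], folds, seed)
  library <- build_library(corpus)
  rows <- list()
  for (lk in losses) {
    for (D in days_eval) {
      preds <- list(); truth <- list()
      for (f in seq_along(fold_sets)) {
        test_ids <- fold_sets[[f]]
        tr <- which((days == 1L & !ids %in% test_ids) |
                      (days > 1L & days <= D))
        te <- which(days == 1L & ids %in% test_ids)
        epochs_fold <- max(epochs, ceiling(min_updates / length(tr)))
        dec <- train_linear_decoder(
          lapply(fused$trials[tr], `[[`, "features"),
          lapply(fused$trials[tr], function(x) velocity_matrix(x$label)),
          loss = sim_loss_spec(lk),
          cfg = train_config(epochs = epochs_fold, lr = lr, patience = 40L,
                             seed = derive_seed(seed, "mdtrain", lk, D, f)))
        for (k in te) {
          preds[[length(preds) + 1L]] <- predict(dec, fused$trials[[k]]$features)
          truth[[length(truth) + 1L]] <- fused$trials[[k]]
        }
      }
      cc <- mean(mapply(function(p, t) cc_metric(p, t$v_actual), preds, truth))
      correct <- mapply(function(p, t)
        recognize(p, library, truth = t$id)$top1_correct, preds, truth)
      rows[[length(rows) + 1L]] <-
        data.frame(loss = lk, days = D, cc = cc,
                   recognition_rate = mean(correct))
    }
  }
  structure(list(summary = do.call(rbind, rows), seed = seed,
                 n_days = n_days),
            class = "multiday_experiment")
}

#' @export
print.multiday_experiment <- function(x, ...) {
  cat("Multi-day fusion simulation:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
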
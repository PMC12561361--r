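# Leave-one-character-out cross-validation for trajectory decoders.

#' Leave-one-character-out cross-validation
#'
#' One fold per character: all repetitions of the held-out character are
#' excluded from that fold's training set (audited by id), the decoder is
#' trained on the rest and evaluated on the held-out repetitions. Fold
#' order is the sorted character set, so assignment is deterministic.
#'
#' @param dataset a [simulate_session()] object, a [multiday_fuse()]
#'   dataset, or a plain list of trials (each with `id`, `rep`, `features`,
#'   `label`).
#' @param loss a [loss_spec()].
#' @param cfg a [train_config()].
#' @param decoder `"linear"`, `"lstm"`, or `"kalman"`.
#' @return object of class `loco_cv`: `metrics` data frame (per trial:
#'   `id`, `rep`, `fold`, `cc`, `mse`, `ndtw`), `decoded` (list of
#'   predicted velocity matrices), `train_sizes` (per fold).
#' @export
crossval_loco <- function(dataset, loss = loss_spec(), cfg = train_config(),
                          decoder = c("linear", "lstm", "kalman")) {
  decoder <- match.arg(decoder)
  trials <- if (inherits(dataset, c("session", "fused_dataset")))
    dataset$trials else dataset
  ids <- vapply(trials, `[[`, character(1L), "id")
  chars <- sort(unique(ids))
  metrics <- list(); decoded <- vector("list", length(trials))
  train_sizes <- integer(0)
  for (f in seq_along(chars)) {
    held <- chars[f]
    te <- which(ids == held)
    if (length(te) == 0L) {
      warning("character '", held, "' has no repetitions; skipping fold")
      next
    }
    tr <- which(ids != held)
    train_sizes[f] <- length(tr)
    feats <- lapply(trials[tr], `[[`, "features")
    targs <- lapply(trials[tr], function(x) velocity_matrix(x$label))
    model <- switch(decoder,
      linear = train_linear_decoder(feats, targs, loss = loss,
        cfg = train_config(epochs = cfg$epochs, lr = cfg$lr,
                           seed = derive_seed(cfg$seed, "fold", f),
                           noise_scale = cfg$noise_scale,
                           patience = cfg$patience)),
      lstm = train_decoder(feats, targs, loss = loss,
        cfg = train_config(epochs = cfg$epochs, lr = cfg$lr,
                           hidden = cfg$hidden,
                           seed = derive_seed(cfg$seed, "fold", f),
                           noise_scale = cfg$noise_scale,
                           patience = cfg$patience)),
      kalman = fit_kalman(targs, feats))
    for (k in te) {
      pred <- predict(model, trials[[k]]$features)
      decoded[[k]] <- pred
      lab <- velocity_matrix(trials[[k]]$label)
      metrics[[length(metrics) + 1L]] <-
        data.frame(id = held, rep = trials[[k]]$rep, fold = f,
                   cc = cc_metric(pred, lab), mse = mse_metric(pred, lab),
                   ndtw = normalized_dtw(lab, pred))
    }
  }
  structure(list(metrics = do.call(rbind, metrics), decoded = decoded,
                 train_sizes = train_sizes, decoder = decoder, loss = loss),
            class = "loco_cv")
}

#' @export
print.loco_cv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-character-out CV (%s, %s loss): %d folds, %d trials\n",
    x$decoder, x$loss$kind, length(x$train_sizes), nrow(x$metrics)))
  cat(sprintf("  mean CC %.3f, mean MSE %.4g, mean normalized DTW %.4g\n",
              mean(x$metrics$cc), mean(x$metrics$mse), mean(x$metrics$ndtw)))
  invisible(x)
}
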
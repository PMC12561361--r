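test_that("the Kalman update reproduces the hand recursion and recovers exact systems", {
  # scalar system stepped through predict/gain/update by hand:
  # xp = 0, Pp = 2, K = 2/3, x1 = K * 2 = 4/3
  m <- list(A = matrix(1), H = matrix(1), Q = matrix(1), R = matrix(1))
  x1 <- kalman_decode(m, matrix(2, 1, 1), x0 = 0, P0 = matrix(1))
  expect_equal(x1[1, 1], 4 / 3, tolerance = 1e-12)

  set.seed(5)
  A <- rbind(c(0.9, 0.1, 0.05), c(-0.2, 0.8, -0.1), c(0, 0, 1))
  H <- matrix(rnorm(12), 4, 3)
  states <- list(); obs <- list()
  for (tr in 1:6) {
    x <- c(rnorm(2), 1)
    XS <- NULL; ZS <- NULL
    for (t in 1:12) {
      XS <- rbind(XS, x[1:2]); ZS <- rbind(ZS, as.numeric(H %*% x))
      x <- as.numeric(A %*% x)
    }
    states[[tr]] <- XS; obs[[tr]] <- ZS
  }
  fit <- fit_kalman(states, obs)
  expect_lt(max(abs(fit$A - A)), 1e-6)
  expect_lt(max(abs(fit$H - H)), 1e-6)
  expect_true(all(eigen(fit$Q, symmetric = TRUE)$values > -1e-8))
  expect_true(all(eigen(fit$R, symmetric = TRUE)$values > -1e-8))
  dec <- suppressWarnings(predict(fit, obs[[2]]))
  expect_lt(max(abs(dec - states[[2]])), 1e-6)

  # huge observation noise -> gain ~ 0 -> pure prediction dynamics
  m2 <- list(A = matrix(0.5), H = matrix(1), Q = matrix(0), R = matrix(1e12))
  out <- kalman_decode(m2, matrix(rnorm(5), 5, 1), x0 = 8, P0 = matrix(0))
  expect_equal(out[, 1], 8 * 0.5^(1:5), tolerance = 1e-4)

  # white-noise states carry no dynamics
  set.seed(6)
  wn <- lapply(1:4, function(i) matrix(rnorm(120), 60))
  ob <- lapply(wn, function(s) s %*% t(matrix(rnorm(10), 5, 2)))
  fit_wn <- fit_kalman(wn, ob)
  expect_lt(max(abs(fit_wn$A[1:2, 1:2])), 0.2)
})

test_that("LSTM backpropagation matches finite differences", {
  set.seed(7)
  params <- handbci:::lstm_init(3, 4, 2, seed = 9)
  X <- matrix(rnorm(18), 6)
  Y <- matrix(rnorm(12), 6)
  for (ls in list(loss_spec("mse"), loss_spec("dilate", gamma = 0.05))) {
    fw <- handbci:::lstm_forward(params, X)
    lv <- handbci:::loss_value_grad(fw$Y, Y, ls)
    gr <- handbci:::lstm_backward(params, X, fw, lv$grad)
    loss_at <- function(p) {
      yy <- handbci:::lstm_forward(p, X)$Y
      handbci:::loss_value_grad(yy, Y, ls)$value
    }
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-6
        expect_equal(gr[[nm]][i], (loss_at(pp) - loss_at(pm)) / 2e-6,
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("decoder training converges, is seeded, and decodes deterministically", {
  set.seed(8)
  X <- matrix(rnorm(60), 20); Y <- matrix(rnorm(40), 20)
  dec <- train_decoder(list(X), list(Y), loss_spec("mse"),
                       train_config(epochs = 150, hidden = 16, seed = 1,
                                    patience = 150))
  sm <- stats::filter(dec$history, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(tail(sm, 1), sm[1])             # smoothed loss decreases
  expect_true(all(diff(sm) < 0.05))         # no blow-ups

  dec2 <- train_decoder(list(X), list(Y), loss_spec("mse"),
                        train_config(epochs = 150, hidden = 16, seed = 1,
                                     patience = 150))
  expect_identical(dec$history, dec2$history)  # seeded reproducibility

  p1 <- predict(dec, X)
  expect_identical(p1, predict(dec, X))
  expect_equal(nrow(p1), nrow(X))
  ks <- decode(dec, X)
  expect_s3_class(ks, "kinematic_series")
  expect_equal(velocity_matrix(ks), p1)

  # recoverable linear map: features = W v + small noise, MSE training
  enc <- make_linear_encoder(24, seed = 3)
  trials <- lapply(letter_corpus()$templates[1:6], function(tp) {
    v <- velocity_matrix(synthesize_kinematics(tp))
    f <- linear_encode(v, enc) + matrix(rnorm(nrow(v) * 24, 0, 0.02), nrow(v))
    list(v = v, f = f)
  })
  fitted <- train_decoder(lapply(trials, `[[`, "f"), lapply(trials, `[[`, "v"),
                          loss_spec("mse"),
                          train_config(epochs = 60, hidden = 32, lr = 0.005,
                                       seed = 2, patience = 60))
  ccs <- vapply(trials, function(tr)
    cor(as.vector(predict(fitted, tr$f)), as.vector(tr$v)), numeric(1))
  expect_gte(mean(ccs), 0.95)
})

test_that("under misalignment DILATE fits the label shape better than MSE", {
  ses <- tiny_session(n_chars = 12L, repetitions = 2L, noise_sd = 0.5, seed = 21L)
  feats <- lapply(ses$trials, `[[`, "features")
  targs <- lapply(ses$trials, function(x) velocity_matrix(x$label))
  ndtw_of <- function(kind) {
    dec <- train_linear_decoder(feats[1:16], targs[1:16],
                                loss_spec(kind, zscore = FALSE),
                                train_config(epochs = 120, lr = 0.005,
                                             seed = 4, patience = 40))
    mean(vapply(17:24, function(k)
      normalized_dtw(targs[[k]], predict(dec, feats[[k]])), numeric(1)))
  }
  expect_lt(ndtw_of("dilate"), ndtw_of("mse"))
})

test_that("leave-one-character-out folds exclude every held-out repetition", {
  ses <- tiny_session(n_chars = 5L, repetitions = 3L, seed = 9L)
  cv <- crossval_loco(ses, loss_spec("mse", zscore = FALSE),
                      train_config(epochs = 3, seed = 1), decoder = "linear")
  expect_equal(length(cv$train_sizes), 5L)
  expect_true(all(cv$train_sizes == 12L))  # 4 characters x 3 reps
  expect_equal(nrow(cv$metrics), 15L)
  expect_true(all(table(cv$metrics$id) == 3L))
  # fold of each trial never contains its own character in training
  expect_true(all(cv$metrics$fold == as.integer(factor(cv$metrics$id))))
  cv2 <- crossval_loco(ses, loss_spec("mse", zscore = FALSE),
                       train_config(epochs = 3, seed = 1), decoder = "linear")
  expect_identical(cv$metrics, cv2$metrics)  # deterministic assignment
})
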
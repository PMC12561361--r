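test_that("timeline resampling preserves the written shape exactly", {
  ks <- synthesize_kinematics(letter_corpus()$templates$L, total_T = 3)
  P <- cbind(ks$x, ks$y)
  n <- nrow(P)
  # identity draw reproduces the input
  idt <- resample_timeline(P, origin = ks$origin, times = as.numeric(1:n))
  expect_equal(idt$P, P, tolerance = 1e-12)
  expect_equal(idt$V, velocity_matrix(ks), tolerance = 1e-9)
  # random draws stay on the space-time polyline
  rs <- resample_timeline(ks, seed = 3)
  path <- rbind(ks$origin, P)
  dist_to_polyline <- function(q) {
    min(vapply(seq_len(nrow(path) - 1), function(k) {
      a <- path[k, ]; b <- path[k + 1, ]
      ab <- b - a
      t <- sum((q - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(max(t, 0), 1)
      sqrt(sum((a + t * ab - q)^2))
    }, numeric(1)))
  }
  expect_lt(max(apply(rs$P, 1, dist_to_polyline)), 1e-9)
  # integrating V' reproduces the resampled endpoint displacement
  expect_equal(ks$origin + colSums(rs$V) / ks$fs, rs$P[n, ], tolerance = 1e-9)
  expect_equal(rs$P[n, ], P[n, ], tolerance = 1e-9)  # endpoint clamped
})

test_that("the linear encoder is linear with frozen weights", {
  enc <- make_linear_encoder(8, seed = 2)
  expect_identical(enc$W, make_linear_encoder(8, seed = 2)$W)
  V <- rand_seq(10, 2)
  expect_equal(linear_encode(matrix(0, 5, 2), enc), matrix(0, 5, 8))
  expect_equal(linear_encode(2 * V, enc), 2 * linear_encode(V, enc))
  expect_equal(dim(linear_encode(V, enc)), c(10L, 8L))
})

test_that("the delayed-copy landscape separates the MSE and DILATE minima", {
  ref <- toy_reference_input()
  expect_equal(sum(ref$y), 100)  # mean 1 baseline
  expect_equal(which(ref$x > 0), which(ref$y > 0) + 8)

  ls <- toy_landscape()
  expect_equal(unname(ls$argmin$mse), c(0, 1))
  expect_equal(unname(ls$argmin$dilate), c(1, 0))

  # MSE surface is the quadratic whose grid argmin matches the closed-form
  # least-squares solution rounded to the grid
  fit <- lm(ref$y ~ ref$x)
  ab <- c(coef(fit)[2], coef(fit)[1])
  rounded <- round(ab / 0.1) * 0.1
  expect_equal(unname(ls$argmin$mse), unname(rounded))
  mse_direct <- function(a, b) mean((a * ref$x + b - ref$y)^2)
  expect_equal(ls$surfaces$mse["a=0.5", "b=-0.5"], mse_direct(0.5, -0.5))

  # zero delay: both losses minimize at the identity (1, 0)
  ls0 <- toy_landscape(y = ref$y, x = ref$y)
  expect_equal(unname(ls0$argmin$mse), c(1, 0))
  expect_equal(unname(ls0$argmin$dilate), c(1, 0))

  expect_error(toy_landscape(a_grid = seq(0.2, 2, 0.1)), "include 0 and 1")
})

test_that("multi-day fusion z-scores per day and audits its folds", {
  s1 <- tiny_session(n_chars = 4L, repetitions = 2L, seed = 31L)
  corpus2 <- lapply(1:4, function(k) random_glyph(900 + k, n_strokes = 2L))
  s2 <- simulate_session(corpus2, encoder = s1$encoder, repetitions = 2L,
                         day = 2L, noise_sd = 0.5, seed = 32L)
  fused <- multiday_fuse(list(s1, s2))
  expect_equal(length(fused$trials), length(s1$trials) + length(s2$trials))
  for (d in 1:2) {
    feats <- do.call(rbind, lapply(Filter(function(tr) tr$day == d,
                                          fused$trials), `[[`, "features"))
    expect_lt(max(abs(colMeans(feats))), 1e-10)
    expect_equal(apply(feats, 2, sd), rep(1, ncol(feats)), tolerance = 1e-10)
  }
  # each fold holds out exactly one character per day
  ids_by_day <- list(unique(vapply(s1$trials, `[[`, character(1), "id")),
                     vapply(corpus2, `[[`, character(1), "id"))
  for (f in fused$folds) {
    expect_equal(length(f), 2L)
    expect_true(f[1] %in% ids_by_day[[1]] && f[2] %in% ids_by_day[[2]])
  }
  expect_equal(length(fused$folds), 4L)
})

test_that("day drift changes gains but not the shared encoder", {
  corpus <- letter_corpus()$templates[1:3]
  enc <- make_linear_encoder(12, seed = 5)
  d1 <- simulate_session(corpus, encoder = enc, repetitions = 1L,
                         day = 1L, noise_sd = 0, seed = 7)
  d2 <- simulate_session(corpus, encoder = enc, repetitions = 1L,
                         day = 2L, noise_sd = 0, seed = 7)
  expect_identical(d1$encoder$W, d2$encoder$W)
  ratio <- d2$trials[[1]]$features / d1$trials[[1]]$features
  expect_gt(sd(colMeans(abs(d2$trials[[1]]$features - d1$trials[[1]]$features))), 0)
  expect_false(isTRUE(all.equal(d1$trials[[1]]$features,
                                d2$trials[[1]]$features)))
})

test_that("a scaled misalignment experiment runs end to end reproducibly", {
  corpus <- structure(list(templates = letter_corpus()$templates[1:6]),
                      class = "glyph_corpus")
  ex <- run_misalignment_experiment(corpus, folds = 3L, seed = 2L,
                                    repetitions = 1L, n_channels = 24L,
                                    epochs = 30L)
  expect_equal(sort(ex$summary$loss), c("dilate", "mse"))
  expect_true(all(ex$summary$recognition_rate >= 0 &
                    ex$summary$recognition_rate <= 1))
  expect_true(all(is.finite(ex$summary$cc)))
  expect_equal(nrow(ex$trials), 12L)  # 6 glyphs x 1 rep x 2 losses
  ex2 <- run_misalignment_experiment(corpus, folds = 3L, seed = 2L,
                                     repetitions = 1L, n_channels = 24L,
                                     epochs = 30L)
  expect_identical(ex$summary, ex2$summary)
})
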
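# Shared short raw recording with ground-truth spikes (2 s trial, 3 channels).
raw_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ks <- synthesize_kinematics(letter_corpus()$templates$A, total_T = 2)
      tun <- tuning_spec(n_channels = 3L, baseline_hz = 30, depth_hz = 60,
                         snr = 5, seed = 2L)
      cache <<- list(rec = simulate_raw_recording(ks, tun, seed = 4L),
                     ks = ks, tun = tun)
    }
    cache
  }
})

test_that("ESA is zero-preserving, homogeneous, and tracks the firing rate", {
  fx <- raw_fixture()
  zero <- raw_recording(matrix(0, 2, 30000), 30000)
  expect_true(all(extract_esa(zero)$data == 0))
  one <- raw_recording(fx$rec$data[1, , drop = FALSE], 30000)
  doubled <- raw_recording(2 * fx$rec$data[1, , drop = FALSE], 30000)
  expect_equal(extract_esa(doubled)$data, 2 * extract_esa(one)$data,
               tolerance = 1e-8)
  esa <- extract_esa(fx$rec)
  expect_equal(esa$fs, 1000)
  v <- velocity_matrix(fx$ks)
  tt <- fx$rec$t0_s + (seq_len(ncol(esa$data)) - 1) / 1000
  kin_idx <- pmin(pmax(floor((tt + 0.4) * 20) + 1, 1), nrow(v))
  for (ch in 1:3) {
    rate <- pmax(0, 30 + 60 * (v[kin_idx, ] %*% fx$tun$pd[ch, ]))
    expect_gte(cor(esa$data[ch, ], rate), 0.5)
  }
  expect_error(extract_esa(raw_recording(matrix(0, 1, 100), 30000)), "warm-up")
})

test_that("SBP passes its band and rejects low frequencies", {
  t30 <- seq(1 / 30000, 1, by = 1 / 30000)
  hi <- extract_sbp(raw_recording(matrix(sin(2 * pi * 500 * t30), 1), 30000))
  lo <- extract_sbp(raw_recording(matrix(sin(2 * pi * 50 * t30), 1), 30000))
  expect_equal(hi$fs, 2000)
  expect_gte(mean(hi$data) / mean(lo$data), 10)
  zero <- raw_recording(matrix(0, 1, 30000), 30000)
  expect_true(all(extract_sbp(zero)$data == 0))
})

test_that("LFP band powers concentrate a 15 Hz tone in the 12-23 Hz band", {
  t30 <- seq(1 / 30000, 1, by = 1 / 30000)
  bands <- extract_lfp_bands(raw_recording(matrix(sin(2 * pi * 15 * t30), 1), 30000))
  pw <- vapply(bands, function(b) mean(b$data), numeric(1))
  expect_true(all(pw >= 0))
  expect_true(all(pw["12-23"] >= 5 * pw[names(pw) != "12-23"]))
  zero <- extract_lfp_bands(raw_recording(matrix(0, 1, 30000), 30000))
  expect_true(all(vapply(zero, function(b) all(b$data == 0), logical(1))))
})

test_that("LMP is the windowed mean of the LFP", {
  const <- neural_stream(matrix(3, 1, 2000), 2000)
  expect_true(all(extract_lmp(const)$data == 3))
  imp <- neural_stream(matrix(c(1, rep(0, 1999)), 1), 2000)
  lmp <- extract_lmp(imp)
  expect_equal(as.numeric(lmp$data), c(1 / 100, rep(0, 19)))  # 100-sample window
  expect_equal(ncol(lmp$data), 2000 %/% 100)
})

test_that("threshold crossings recover ground-truth spikes and are monotone in k", {
  fx <- raw_fixture()
  tc45 <- threshold_crossings(fx$rec, 4.5)
  tc62 <- threshold_crossings(fx$rec, 6.25)
  for (ch in 1:3) {
    truth <- fx$rec$spike_times[[ch]] + fx$rec$t0_s
    det <- tc45$times[[ch]]
    recovery <- mean(vapply(truth, function(s) any(abs(det - s) < 2e-3),
                            logical(1)))
    expect_gte(recovery, 0.9)
    expect_lte(length(tc62$times[[ch]]), length(tc45$times[[ch]]))
  }
  zero <- raw_recording(matrix(0, 1, 30000), 30000)
  expect_equal(lengths(threshold_crossings(zero, 4.5)$times), 0L)
})

test_that("cMUA is nonnegative and agrees with ESA on binned features", {
  fx <- raw_fixture()
  cm <- extract_cmua(fx$rec)
  expect_true(all(cm$data >= 0))
  esa <- extract_esa(fx$rec)
  nb <- length(fx$ks$vx)
  b_cm <- bin_and_lag(cm, nb)
  b_esa <- bin_and_lag(esa, nb)
  for (ch in 1:3)
    expect_gte(cor(b_cm$values[ch, ], b_esa$values[ch, ]), 0.8)
})

test_that("binning honors the lag, conserves constants, and demands padding", {
  const <- neural_stream(matrix(2.5, 1, 3000), 1000, t0_s = -0.5)
  fb <- bin_and_lag(const, n_bins = 40)
  expect_equal(as.numeric(fb$values), rep(2.5, 40))
  expect_equal(ncol(fb$values), 40L)
  imp <- neural_stream(matrix(0, 1, 3000), 1000, t0_s = -0.5)
  imp$data[1, 1001] <- 1  # impulse at trial time 0.5 s
  hit <- which(bin_and_lag(imp, 40)$values[1, ] > 0)
  hit_times <- (hit - 1) * 0.05
  expect_true(all(hit_times > 0.5 + 0.3 - 1e-9))          # >= lag later
  expect_true(all(hit_times <= 0.5 + 0.3 + 0.2 + 1e-9))   # within lag + bin
  unpadded <- neural_stream(matrix(1, 1, 3000), 1000, t0_s = 0)
  expect_error(bin_and_lag(unpadded, 40), "padding")
  counts <- neural_stream(matrix(1, 1, 3000), 1000, t0_s = -0.5)
  expect_equal(as.numeric(bin_and_lag(counts, 5, aggregate = "sum")$values),
               rep(200, 5))  # 200 samples per 200 ms window
})

test_that("channel z-scoring freezes training statistics for test data", {
  set.seed(12)
  train <- feature_matrix(matrix(rnorm(300, mean = 4), 3))
  zs <- zscore_channels(train)
  expect_equal(rowMeans(zs$values), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(zs$values, 1, sd), rep(1, 3), tolerance = 1e-12)
  test <- feature_matrix(matrix(rnorm(300, mean = 9), 3))
  zt <- zscore_channels(test, stats = attr(zs, "stats"))
  expect_gt(mean(zt$values), 1)  # shifted test set keeps its shift
  flat <- zscore_channels(feature_matrix(matrix(5, 2, 10)))
  expect_true(all(flat$values == 0))
})

test_that("noise augmentation has the requested per-channel scale and seed", {
  set.seed(13)
  f <- matrix(rnorm(2 * 10000), 2)
  f[2, ] <- 3 * f[2, ]
  expect_identical(augment_noise(f, 0), f)
  a1 <- augment_noise(f, 0.4, seed = 7)
  a2 <- augment_noise(f, 0.4, seed = 7)
  expect_identical(a1, a2)
  added_sd <- apply(a1 - f, 1, sd)
  expect_equal(added_sd, 0.4 * apply(f, 1, sd), tolerance = 0.1)
})
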
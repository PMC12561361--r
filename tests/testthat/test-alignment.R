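test_that("pairwise cost matches the squared-Euclidean definition", {
  expect_equal(pairwise_cost(matrix(c(0, 0), 1), matrix(c(0, 0), 1)),
               matrix(0, 1, 1))
  expect_equal(pairwise_cost(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1))),
               matrix(c(1, 2), 2, 1))
  set.seed(1)
  y <- rand_seq(4, 2); z <- rand_seq(3, 2)
  direct <- outer(seq_len(4), seq_len(3),
                  Vectorize(function(i, j) sum((y[i, ] - z[j, ])^2)))
  expect_equal(pairwise_cost(y, z), direct)
  expect_equal(pairwise_cost(y, z), t(pairwise_cost(z, y)))
  expect_error(pairwise_cost(y, rand_seq(3, 3)), "dimensionality")
})

test_that("dtw equals brute-force path enumeration on short sequences", {
  expect_equal(dtw(0, 3)$distance, 9)
  set.seed(2)
  for (rep in 1:8) {
    m <- sample(1:5, 1); n <- sample(1:5, 1); d <- sample(1:2, 1)
    y <- rand_seq(m, d); z <- rand_seq(n, d)
    D <- pairwise_cost(y, z)
    a <- dtw(y, z)
    expect_equal(a$distance, enum_min(D), tolerance = 1e-12)
    expect_equal(a$distance, path_cost(a$path, D))  # returned path attains it
    expect_equal(a$path[1, ], c(1, 1))
    expect_equal(a$path[nrow(a$path), ], c(m, n))
    steps <- diff(a$path)
    expect_true(all(steps >= 0) && all(steps <= 1) && all(rowSums(steps) >= 1))
  }
  s <- rand_seq(6, 2)
  id <- dtw(s, s)
  expect_equal(id$distance, 0)
  expect_equal(id$path, cbind(1:6, 1:6))
  expect_error(dtw(numeric(0), 1))
})

test_that("fast_dtw upper-bounds dtw and matches it on smooth sequences", {
  t <- seq(0, 2 * pi, length.out = 32)
  a <- matrix(sin(t)); b <- matrix(sin(t + 0.4))
  expect_equal(fast_dtw(a, a, 2)$distance, 0)
  expect_equal(fast_dtw(a, b, 2)$distance, dtw(a, b)$distance)
  set.seed(3)
  for (rep in 1:5) {
    y <- rand_seq(40); z <- rand_seq(37)   # adversarial spiky pair
    expect_gte(fast_dtw(y, z, 1)$distance, dtw(y, z)$distance - 1e-10)
  }
  expect_error(fast_dtw(a, b, 0), "radius")
})

test_that("soft_min is a stable lower bound of min", {
  expect_equal(soft_min(rep(3, 4), 0.5), 3 - 0.5 * log(4))
  expect_equal(soft_min(c(0, 1), 1), -log(1 + exp(-1)))
  expect_lt(abs(soft_min(c(0, 1000), 0.001)), 1e-9)  # no overflow
  set.seed(4)
  v <- rnorm(6)
  expect_lte(soft_min(v, 0.2), min(v))
  expect_error(soft_min(v, 0), "gamma")
  expect_error(soft_min(numeric(0), 1), "non-empty")
})

test_that("soft_dtw matches path enumeration and approaches dtw as gamma -> 0", {
  set.seed(5)
  for (rep in 1:6) {
    y <- rand_seq(3, 2); z <- rand_seq(3, 2)
    D <- pairwise_cost(y, z)
    g <- runif(1, 0.1, 1)
    expect_equal(soft_dtw(y, z, g), enum_softdtw(D, g), tolerance = 1e-8)
    expect_lte(soft_dtw(y, z, g), dtw(y, z)$distance)
  }
  y <- rand_seq(8); z <- rand_seq(8)
  expect_lte(abs(soft_dtw(y, z, 1e-4) - dtw(y, z)$distance), 1e-2)
})

test_that("relaxed_path is the Gibbs path average and the soft-DTW gradient", {
  set.seed(6)
  for (rep in 1:4) {
    y <- rand_seq(3, 2); z <- rand_seq(4, 2)
    g <- runif(1, 0.2, 1)
    E <- relaxed_path(y, z, g)
    expect_equal(unclass(E), enum_gibbs(pairwise_cost(y, z), g),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(E >= 0 & E <= 1 + 1e-12))
    expect_equal(E[1, 1], 1)
    expect_equal(E[3, 4], 1)
  }
  # central finite differences on the cost matrix
  y <- rand_seq(4); z <- rand_seq(4)
  D <- pairwise_cost(y, z)
  g <- 0.5
  E <- relaxed_path(y, z, g)
  fd <- matrix(NA_real_, 4, 4)
  softdtw_of <- function(DD) handbci:::cpp_softdtw(DD, g)$value
  for (i in 1:4) for (j in 1:4) {
    Dp <- D; Dp[i, j] <- Dp[i, j] + 1e-6
    Dm <- D; Dm[i, j] <- Dm[i, j] - 1e-6
    fd[i, j] <- (softdtw_of(Dp) - softdtw_of(Dm)) / 2e-6
  }
  expect_equal(unclass(E), fd, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("soft_tdi matches the enumeration expectation of the time penalty", {
  expect_equal(soft_tdi(0, 0, gamma = 0.1), 0)  # single cell, omega(1,1) = 0
  set.seed(7)
  for (norm in c(TRUE, FALSE)) {
    y <- rand_seq(3, 2); z <- rand_seq(3, 2)
    g <- 0.4
    E <- enum_gibbs(pairwise_cost(y, z), g)
    expect_equal(soft_tdi(y, z, g, normalize = norm),
                 sum(E * omega_of(3, 3, norm)), tolerance = 1e-8)
    expect_gte(soft_tdi(y, z, g, normalize = norm), 0)
  }
})

test_that("dilate_loss combines shape and time terms and stays finite", {
  set.seed(8)
  y <- rand_seq(5, 2); z <- rand_seq(5, 2)
  expect_equal(dilate_loss(y, z, alpha = 1, gamma = 0.2),
               soft_dtw(y, z, 0.2))
  expect_equal(dilate_loss(y, z, alpha = 0, gamma = 0.2),
               soft_tdi(y, z, 0.2))
  y3 <- rand_seq(3); z3 <- rand_seq(3)
  D <- pairwise_cost(y3, z3)
  g <- 0.001
  expect_equal(dilate_loss(y3, z3, alpha = 0.5, gamma = g),
               0.5 * enum_softdtw(D, g) +
                 0.5 * sum(enum_gibbs(D, g) * omega_of(3, 3)),
               tolerance = 1e-8)
  # continuity / no NaN over the hyperparameter box
  for (a in c(0.1, 0.5, 0.9))
    for (g in c(1e-4, 1e-2, 1))
      expect_true(is.finite(dilate_loss(y, z, alpha = a, gamma = g)))
})

test_that("dilate_grad matches central finite differences", {
  set.seed(9)
  y <- rand_seq(5, 2); z <- rand_seq(4, 2)
  for (g in c(0.5, 0.01)) {
    res <- dilate_grad(y, z, alpha = 0.4, gamma = g)
    num <- z * 0
    for (j in 1:4) for (k in 1:2) {
      zp <- z; zp[j, k] <- zp[j, k] + 1e-6
      zm <- z; zm[j, k] <- zm[j, k] - 1e-6
      num[j, k] <- (dilate_loss(y, zp, 0.4, g) - dilate_loss(y, zm, 0.4, g)) / 2e-6
    }
    expect_equal(res$grad, num, tolerance = 1e-4)
  }
})

test_that("warp_to_reference follows the min-index rule along the hard path", {
  ref <- matrix(c(0, 1, 2, 3), ncol = 1)
  expect_equal(warp_to_reference(ref, ref), ref)
  # middle element duplicated: alignment read off the dtw path by hand
  pred <- matrix(c(0, 1, 1, 2, 3), ncol = 1)
  out <- warp_to_reference(ref, pred)
  path <- dtw(ref, pred)$path
  idx <- vapply(1:4, function(i) min(path[path[, 1] == i, 2]), integer(1))
  expect_equal(out, pred[idx, , drop = FALSE])
  expect_equal(nrow(out), 4L)
  expect_true(all(out %in% ref))
  # constant prediction stays constant
  expect_equal(warp_to_reference(ref, matrix(1, 6, 1)), matrix(1, 4, 1))
})

test_that("alignment offsets are bin multiples with the expected delay mode", {
  s <- matrix(sin(seq(0, 3 * pi, length.out = 40)), ncol = 1)
  same <- alignment_offsets(s, s)
  expect_true(all(same$per_point_offsets == 0))
  expect_equal(same$sd_ms, 0)
  delayed <- rbind(matrix(s[1], 2, 1), s[1:38, , drop = FALSE])
  off <- alignment_offsets(s, delayed, bin_ms = 50)
  expect_true(all(off$per_point_offsets %% 50 == 0))
  mode <- as.integer(names(which.max(table(abs(off$per_point_offsets)))))
  expect_equal(mode, 100)
})

test_that("normalized dtw divides by the optimal path length", {
  s <- rand_seq(6)
  expect_equal(normalized_dtw(s, s), 0)
  expect_equal(normalized_dtw(0, 3), 9)
  set.seed(10)
  y <- rand_seq(5); z <- rand_seq(5)
  a <- dtw(y, z)
  expect_equal(a$distance, enum_min(pairwise_cost(y, z)))  # oracle distance
  expect_equal(normalized_dtw(y, z), a$distance / nrow(a$path))
})

test_that("alignment paths export as index-pair tables", {
  p <- dtw(rand_seq(4), rand_seq(5))$path
  f <- tempfile(fileext = ".csv")
  alignment_path_df(p, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(p))
  expect_named(df, c("i", "j"))
})
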
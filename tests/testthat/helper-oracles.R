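# Independent oracles used across the suite.

# Exhaustive enumeration of admissible alignment paths from (1,1) to (m,n).
enum_paths <- function(m, n) {
  res <- list()
  rec <- function(i, j, cells) {
    if (i == m && j == n) {
      res[[length(res) + 1L]] <<- cells
      return(invisible())
    }
    if (i < m) rec(i + 1L, j, rbind(cells, c(i + 1L, j)))
    if (j < n) rec(i, j + 1L, rbind(cells, c(i, j + 1L)))
    if (i < m && j < n) rec(i + 1L, j + 1L, rbind(cells, c(i + 1L, j + 1L)))
  }
  rec(1L, 1L, matrix(c(1L, 1L), 1L))
  res
}

path_cost <- function(cells, D) sum(D[cells])

# Enumeration-based soft-DTW, Gibbs path average, and soft-TDI.
enum_softdtw <- function(D, gamma) {
  costs <- vapply(enum_paths(nrow(D), ncol(D)), path_cost, numeric(1L), D = D)
  m <- min(costs)  # max-shift, as in the implementation's log-sum-exp
  m - gamma * log(sum(exp(-(costs - m) / gamma)))
}

enum_gibbs <- function(D, gamma) {
  paths <- enum_paths(nrow(D), ncol(D))
  costs <- vapply(paths, path_cost, numeric(1L), D = D)
  w <- exp(-(costs - min(costs)) / gamma); w <- w / sum(w)
  E <- matrix(0, nrow(D), ncol(D))
  for (k in seq_along(paths)) {
    A <- matrix(0, nrow(D), ncol(D)); A[paths[[k]]] <- 1
    E <- E + w[k] * A
  }
  E
}

enum_min <- function(D) {
  min(vapply(enum_paths(nrow(D), ncol(D)), path_cost, numeric(1L), D = D))
}

omega_of <- function(m, n, normalize = TRUE) {
  om <- outer(seq_len(m), seq_len(n), function(i, j) (i - j)^2)
  if (normalize) om / (m * n) else om
}

rand_seq <- function(n, d = 1L) matrix(stats::rnorm(n * d), n, d)

# Small, quickly-synthesized session shared by decoder/simulation tests.
tiny_session <- function(n_chars = 6L, repetitions = 1L, n_channels = 24L,
                         misalign = TRUE, noise_sd = 0.5, seed = 11L) {
  corpus <- letter_corpus()$templates[seq_len(n_chars)]
  simulate_session(corpus, encoder = make_linear_encoder(n_channels, seed = seed),
                   repetitions = repetitions, misalign = misalign,
                   noise_sd = noise_sd, seed = seed)
}
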
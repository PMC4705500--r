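# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary data is stored.

# small random fingerprint matrix with a simple increasing time axis
random_fm <- function(n = 5, p = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rlnorm(n * p, 0, 1), n, p)
    fingerprint_matrix(X, seq(0, 1, length.out = p))
  })
}

# standardised regression problem with a sparse linear truth
sparse_problem <- function(n = 40, p = 60, k = 3, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    beta <- c(rep(1, k), rep(0, p - k))
    y <- as.numeric(X %*% beta) + stats::rnorm(n, 0, noise)
    list(X = X, y = y, beta = beta)
  })
}

# summed per-segment Pearson score used by the warping construction
segment_score <- function(sample, reference, segment_length) {
  m <- length(reference)
  n_seg <- max(2L, as.integer(round((m - 1) / segment_length)))
  bounds <- round(seq(1, m, length.out = n_seg + 1))
  sc <- 0
  for (i in 2:(n_seg + 1)) {
    a <- sample[bounds[i - 1]:bounds[i]]
    b <- reference[bounds[i - 1]:bounds[i]]
    if (stats::sd(a) > 0 && stats::sd(b) > 0)
      sc <- sc + stats::cor(a, b)
  }
  sc
}

# elastic-net objective as written: ||y - b0 - Xb||^2/(2n) + l1|b|_1 + l2|b|_2^2/2
en_objective <- function(X, y, b0, b, l1, l2) {
  r <- y - b0 - as.numeric(X %*% b)
  sum(r^2) / (2 * length(y)) + l1 * sum(abs(b)) + l2 * sum(b^2) / 2
}
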
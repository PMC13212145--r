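# Small fixtures built in code, shared across test files.

# Chain-graph Ising model: beta on consecutive pairs, thresholds centred so
# node prevalences sit near one half (the most informative regime for
# structure recovery).
chain_ising <- function(p = 6, beta = 1.5, tau = -beta) {
  B <- matrix(0, p, p)
  for (i in seq_len(p - 1)) B[i, i + 1] <- B[i + 1, i] <- beta
  ising_model(rep_len(tau, p), B, nodes = sprintf("n%02d", seq_len(p)))
}

# A well-spread 2PL bank for recovery and screening tests.
toy_bank <- function(J = 10, a = seq(0.9, 2.2, length.out = J),
                     b = seq(-2, 2, length.out = J), g = 0) {
  item_bank(sprintf("i%02d", seq_len(J)), a = a, b = b, g = g)
}

# Perfect Guttman (triangular) matrix: person i passes the i easiest items.
guttman_matrix <- function(n_items = 4) {
  X <- matrix(0L, n_items + 1, n_items)
  for (i in seq_len(n_items + 1)) if (i > 1) X[i, seq_len(i - 1)] <- 1L
  colnames(X) <- sprintf("g%02d", seq_len(n_items))
  response_matrix(X, "function")
}

# Brute-force O(k^2) Guttman error count for one response vector given
# items already ordered from easiest to hardest.
guttman_brute <- function(x) {
  k <- length(x)
  cnt <- 0L
  for (e in seq_len(k - 1)) for (h in (e + 1):k)
    if (x[e] == 0 && x[h] == 1) cnt <- cnt + 1L
  cnt
}

# Brute-force Hij from the 2x2 cell counts of an item pair.
hij_brute <- function(xi, xj) {
  n <- length(xi)
  p11 <- mean(xi == 1 & xj == 1)
  pi_ <- mean(xi); pj <- mean(xj)
  cov_ij <- p11 - pi_ * pj
  cov_max <- min(pi_, pj) - pi_ * pj
  cov_ij / cov_max
}

# Brute-force Kendall tau-b with tie correction.
tau_b_brute <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(split(seq_along(x), x), function(ix)
    length(ix) * (length(ix) - 1) / 2))
  ty <- sum(sapply(split(seq_along(y), y), function(iy)
    length(iy) * (length(iy) - 1) / 2))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}
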
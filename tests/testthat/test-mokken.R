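test_that("scalability coefficients: Guttman data give H = 1, independence gives Hij near 0", {
  sc <- scalability_coefficients(guttman_matrix(4))
  expect_equal(sc$H, 1)
  expect_true(all(abs(sc$Hi - 1) < 1e-12))

  set.seed(2)
  X <- matrix(rbinom(40000, 1, 0.5), 20000, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_lt(abs(scalability_coefficients(X)$Hij["a", "b"]), 0.03)

  Xz <- cbind(a = rep(1L, 10), b = rbinom(10, 1, 0.5))
  expect_error(scalability_coefficients(Xz), "zero-variance")
})

test_that("Hij matches brute-force covariance ratios and H is the weighted mean of Hi", {
  X <- matrix(c(1, 0, 0,
                1, 1, 0,
                1, 1, 1,
                0, 1, 0), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("e", "m", "h")))
  sc <- scalability_coefficients(X)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(sc$Hij[i, j], hij_brute(X[, i], X[, j]), tolerance = 1e-12)

  # weighted-mean identities with cov_max weights
  set.seed(5)
  Xr <- generate_irt_responses(toy_bank(6), sim_config(200, seed = 5))
  scr <- scalability_coefficients(Xr)
  p <- colMeans(Xr)
  Cmax <- outer(p, p, pmin) - outer(p, p)
  diag(Cmax) <- NA
  num_i <- rowSums(scr$Hij * Cmax, na.rm = TRUE)
  expect_equal(unname(scr$Hi), unname(num_i / rowSums(Cmax, na.rm = TRUE)))
  expect_equal(scr$H,
               sum((scr$Hij * Cmax)[upper.tri(Cmax)]) /
                 sum(Cmax[upper.tri(Cmax)]))
})

test_that("Guttman error counts match an O(k^2) pair scan and respect popularity order", {
  g <- guttman_matrix(5)
  expect_true(all(guttman_errors(g) == 0))

  set.seed(6)
  X <- generate_irt_responses(toy_bank(8), sim_config(60, seed = 6))
  cnt <- guttman_errors(X)
  ord <- order(-colMeans(X), colnames(X))
  Xo <- unclass(X)[, ord]
  brute <- apply(Xo, 1, guttman_brute)
  expect_identical(unname(cnt), unname(as.integer(brute)))

  # failing the easiest item but passing the rest yields k - 1 errors
  k <- 6
  base <- guttman_matrix(k)
  odd <- rbind(unclass(base)[, ], c(0L, rep(1L, k - 1)))
  rownames(odd) <- sprintf("p%03d", seq_len(nrow(odd)))
  cnt2 <- guttman_errors(response_matrix(odd, "function"))
  expect_equal(unname(cnt2[nrow(odd)]), k - 1L)

  # permutation invariance of the flag set
  cntp <- guttman_errors(response_matrix(odd[sample(nrow(odd)), ], "function"))
  expect_setequal(flag_aberrant_persons(cntp), flag_aberrant_persons(cnt2))
})

test_that("aberrant-person flagging uses the Tukey upper fence", {
  expect_length(flag_aberrant_persons(setNames(rep(3, 10), paste0("p", 1:10))), 0)
  cnts <- setNames(c(rep(2, 19), 20), paste0("p", 1:20))
  expect_identical(flag_aberrant_persons(cnts), "p20")
})

test_that("AISP keeps a strong unidimensional scale and drops a noise item", {
  set.seed(7)
  ib <- toy_bank(8, a = 2, b = seq(-1.5, 1.5, length.out = 8))
  X <- generate_irt_responses(ib, sim_config(1000, seed = 7))
  sel <- aisp_select(X, 0.42)
  expect_setequal(sel$selected, colnames(X))
  expect_gt(sel$H, 0.42)

  Xn <- cbind(unclass(X)[, ], noise = rbinom(1000, 1, 0.5))
  sel2 <- aisp_select(response_matrix(Xn, "function"), 0.42)
  expect_false("noise" %in% sel2$selected)

  # degenerate bound keeps everything positively correlated
  sel0 <- aisp_select(X, 0)
  expect_setequal(sel0$selected, colnames(X))

  # pure noise: empty selection, not an error
  Xind <- matrix(rbinom(2000, 1, 0.5), 500, 4,
                 dimnames = list(NULL, paste0("z", 1:4)))
  expect_length(aisp_select(Xind, 0.42)$selected, 0)
})

test_that("monotonicity checks pass monotone items and catch a constructed violation", {
  set.seed(8)
  X <- generate_irt_responses(toy_bank(8, a = 1.5), sim_config(1000, seed = 8))
  rep1 <- check_monotonicity(X)
  expect_true(all(rep1$testable))
  expect_equal(sum(rep1$n_significant), 0)

  # an item equal to the complement of a high-popularity indicator of the
  # rest score decreases in the rest score
  Xb <- unclass(X)[, ]
  rest <- rowSums(Xb[, -1])
  Xb[, 1] <- as.integer(rest < stats::median(rest))
  rep2 <- check_monotonicity(response_matrix(Xb, "function"))
  expect_gt(rep2$n_significant[1], 0)

  Xc <- cbind(const = rep(1L, 100), ok = rbinom(100, 1, 0.5),
              ok2 = rbinom(100, 1, 0.5))
  rep3 <- check_monotonicity(response_matrix(Xc, "function"))
  expect_false(rep3$testable[rep3$item == "const"])
})
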
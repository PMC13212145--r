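test_that("ising expectations have their symmetry and single-node closed forms", {
  m0 <- ising_model(rep(0, 10), matrix(0, 10, 10))
  ex <- ising_expectation(m0, "exact")
  expect_equal(unname(ex$p), rep(0.5, 10))
  expect_equal(ex$expected_score, 5)

  m1 <- ising_model(0.8, matrix(0, 1, 1))
  expect_equal(unname(ising_expectation(m1, "exact")$p), plogis(0.8))
  expect_error(ising_expectation(ising_model(rep(0, 21), matrix(0, 21, 21)),
                                 "exact"), "20 nodes")
})

test_that("Gibbs and exact expectations agree within Monte-Carlo error on 10 nodes", {
  set.seed(13)
  p <- 10
  B <- matrix(0, p, p)
  for (k in 1:8) {
    ij <- sample(p, 2)
    B[ij[1], ij[2]] <- B[ij[2], ij[1]] <- runif(1, -1, 1)
  }
  mod <- ising_model(rnorm(p, 0, 0.5), B)
  ex <- ising_expectation(mod, "exact")
  gb <- ising_expectation(mod, "gibbs", reps = 20000, seed = 14)
  expect_lt(abs(gb$expected_score - ex$expected_score), 3 * gb$mc_se + 0.05)
  expect_lt(max(abs(gb$p - ex$p)), 0.03)
})

test_that("structure search finds nothing under independence and everything for a strong pair", {
  set.seed(15)
  X <- matrix(rbinom(12000, 1, 0.5), 2000, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  bsl <- bsl_structure_search(response_matrix(X, "risk"), iterations = 5000,
                              seed = 16)
  expect_true(all(bsl$edge_posterior[upper.tri(bsl$edge_posterior)] < 0.5))

  v <- rbinom(500, 1, 0.5)
  X2 <- cbind(a = v, b = v)
  bsl2 <- bsl_structure_search(response_matrix(X2, "risk"),
                               iterations = 2000, seed = 17)
  expect_gt(bsl2$edge_posterior["a", "b"], 0.99)
  expect_warning(bsl_structure_search(response_matrix(X2, "risk"),
                                      iterations = 500, seed = 1),
                 "fewer than 1000")
})

test_that("a planted chain graph is recovered in at least 18 of 20 seeded replicates", {
  mod <- chain_ising(6, beta = 1.5)
  truth <- mod$beta != 0
  hits <- 0
  for (r in 1:20) {
    X <- generate_ising_sample(mod, 2000, "gibbs", seed = 300 + r)
    g <- select_graph(bsl_structure_search(X, iterations = 6000,
                                           seed = 400 + r))
    if (identical(unname(g), unname(truth))) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("edge posteriors are invariant to column permutation up to MCMC error", {
  mod <- chain_ising(5, beta = 1.5)
  X <- generate_ising_sample(mod, 1500, "gibbs", seed = 21)
  perm <- c(3, 1, 5, 2, 4)
  Xp <- response_matrix(unclass(X)[, perm], "risk")
  ep1 <- bsl_structure_search(X, iterations = 8000, seed = 22)$edge_posterior
  ep2 <- bsl_structure_search(Xp, iterations = 8000, seed = 23)$edge_posterior
  ep2 <- ep2[colnames(ep1), colnames(ep1)]
  expect_lt(max(abs(ep1 - ep2)), 0.2)
  expect_identical(select_graph(ep1), select_graph(ep2))
})

test_that("graph selection is strict at the cut and pseudo-likelihood has its empty-graph closed form", {
  ep <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_false(any(select_graph(ep)))
  expect_true(all(select_graph(matrix(1, 3, 3) - diag(3))[upper.tri(diag(3))]))
  expect_false(any(select_graph(matrix(0, 3, 3))))

  set.seed(24)
  X <- matrix(rbinom(600, 1, 0.3), 200, 3,
              dimnames = list(NULL, paste0("v", 1:3)))
  fit <- estimate_ising(response_matrix(X, "risk"), matrix(FALSE, 3, 3))
  expect_equal(unname(fit$tau), unname(qlogis(colMeans(X))))
  expect_true(all(fit$beta == 0))
})

test_that("pseudo-likelihood recovers a two-node interaction and returns a symmetric beta", {
  mod <- ising_model(c(0, 0), matrix(c(0, 1.5, 1.5, 0), 2),
                     nodes = c("a", "b"))
  X <- generate_ising_sample(mod, 5000, "gibbs", seed = 25)
  g <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
  fit <- estimate_ising(X, g)
  expect_lt(abs(fit$beta["a", "b"] - 1.5), 0.2)
  expect_identical(fit$beta, t(fit$beta))
})

test_that("the maximal connected component obeys its size and tie rules", {
  adj <- function(edges, nodes) {
    A <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- TRUE
    A
  }
  nodes <- letters[1:8]
  chain <- adj(Map(c, nodes[-8], nodes[-1]), nodes)
  expect_setequal(maximal_connected_component(chain), nodes)

  two <- adj(list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                  c("f", "g"), c("g", "h")), nodes)
  expect_setequal(maximal_connected_component(two), c("a", "b", "c", "d", "e"))

  empty <- adj(list(), nodes)
  expect_identical(maximal_connected_component(empty), "a")
})
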
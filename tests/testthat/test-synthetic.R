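test_that("IRT response generation is seeded, saturates correctly and rejects bad banks", {
  ib <- toy_bank()
  cfg <- sim_config(n_persons = 50, seed = 7)
  m1 <- generate_irt_responses(ib, cfg)
  m2 <- generate_irt_responses(ib, cfg)
  expect_identical(unclass(m1), unclass(m2))
  expect_identical(orientation(m1), "function")

  sat <- generate_irt_responses(ib, sim_config(20, seed = 1),
                                theta = rep(10, 20))
  expect_true(all(sat == 1L))

  bad <- toy_bank()
  bad$a[1] <- -1
  expect_error(generate_irt_responses(bad, cfg), "discrimination")
})

test_that("observed item proportions match the quadrature-integrated response function", {
  ib <- icf_item_bank()
  m <- generate_irt_responses(ib, sim_config(n_persons = 5000, seed = 11))
  observed <- colMeans(m)
  # independent oracle: numeric integration of the IRF over the N(0,1) trait
  expected <- vapply(seq_len(nrow(ib)), function(j)
    stats::integrate(function(t)
      dnorm(t) * (ib$g[j] + (1 - ib$g[j]) * plogis(ib$a[j] * (t - ib$b[j]))),
      -8, 8)$value, 0)
  expect_lt(max(abs(observed - expected)), 0.02)
})

test_that("Ising sampler matches closed forms and exact enumeration", {
  # independence + symmetry: all marginals near 1/2
  m0 <- ising_model(rep(0, 4), matrix(0, 4, 4))
  X <- generate_ising_sample(m0, 10000, "gibbs", seed = 3)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(colMeans(X) - 0.5) < 3 * se))

  # single node: mean = logistic(tau)
  m1 <- ising_model(1.0, matrix(0, 1, 1))
  X1 <- generate_ising_sample(m1, 20000, "gibbs", seed = 4)
  expect_equal(mean(X1), plogis(1), tolerance = 0.02)

  # 2-node interaction: joint frequencies vs exact enumeration
  b <- matrix(c(0, 2, 2, 0), 2)
  m2 <- ising_model(c(0, 0), b)
  X2 <- generate_ising_sample(m2, 20000, "gibbs", seed = 5)
  counts <- table(factor(paste0(X2[, 1], X2[, 2]),
                         levels = c("00", "01", "10", "11")))
  ex <- icfnet:::ising_exact_probs(m2)
  gof <- suppressWarnings(chisq.test(as.numeric(counts), p = ex$probs))
  expect_gt(gof$p.value, 0.01)

  # exact sampling refused beyond enumeration capacity
  m21 <- ising_model(rep(0, 21), matrix(0, 21, 21))
  expect_error(generate_ising_sample(m21, 5, "exact"), "20 nodes")
})

test_that("Gibbs draws stay within total-variation 0.03 of the exact distribution", {
  tau <- c(0.3, -0.2, 0, 0.4, -0.5)
  B <- matrix(0, 5, 5)
  B[1, 2] <- B[2, 1] <- 1; B[3, 4] <- B[4, 3] <- -0.8
  B[2, 5] <- B[5, 2] <- 0.5
  mod <- ising_model(tau, B)
  S <- generate_ising_sample(mod, 50000, "gibbs", seed = 9, thin = 2)
  ex <- icfnet:::ising_exact_probs(mod)
  kex <- apply(ex$states, 1, paste, collapse = "")
  emp <- table(factor(apply(unclass(S), 1, paste, collapse = ""),
                      levels = kex)) / nrow(S)
  expect_lt(0.5 * sum(abs(as.numeric(emp) - ex$probs)), 0.03)
})

test_that("missingness injection hits the configured rate and is reversible", {
  ib <- toy_bank(43)
  m <- generate_irt_responses(ib, sim_config(300, seed = 2))
  expect_identical(inject_missingness(m, 0), m)

  h <- inject_missingness(m, 0.1, seed = 5)
  n_na <- sum(is.na(h))
  expect_lt(abs(n_na - 1290), 3 * sqrt(300 * 43 * 0.1 * 0.9))
  expect_identical(h, inject_missingness(m, 0.1, seed = 5))
  mask <- attr(h, "miss_mask")
  expect_identical(attr(h, "truth")[!mask], h[!mask])
})

test_that("synthetic cohorts carry the configured marginals and criterion correlations", {
  co <- generate_cohort(sim_config(n_persons = 300, seed = 6))
  expect_equal(nrow(co$covariates), 300)
  expect_lt(abs(mean(co$covariates$age_group == "younger") - 0.62),
            3 * sqrt(0.62 * 0.38 / 300))
  expect_true(all(!is.na(co$covariates)))
  expect_true(all((co$covariates$age >= 70) ==
                    (co$covariates$age_group == "older")))

  # noiseless surrogate scores are exact monotone transforms of theta
  co0 <- generate_cohort(sim_config(n_persons = 100, seed = 8,
                                    criterion_noise_sd = 0))
  expect_equal(cor(co0$theta, co0$criteria$mna_like, method = "spearman"), 1)
  expect_equal(cor(co0$theta, co0$criteria$pgsga_like, method = "spearman"), -1)

  # default noise keeps validity-style correlations in the plausible band
  r_mna <- winsorized_correlation(co$theta, co$criteria$mna_like)$r
  r_pgsga <- winsorized_correlation(co$theta, co$criteria$pgsga_like)$r
  expect_true(r_mna > 0.5 && r_mna < 0.9)
  expect_true(r_pgsga < -0.5 && r_pgsga > -0.9)
})
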
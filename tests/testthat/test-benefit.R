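test_that("node perturbation shifts exactly one threshold by two threshold SDs", {
  mod <- ising_model(c(a = 1, b = 2, c = 3), matrix(0, 3, 3))
  cfg <- perturbation_config(seed = 1)
  shifted <- perturb_node(mod, "a", cfg)
  expect_equal(unname(shifted$tau["a"]), 1 - 2 * sd(mod$tau))
  expect_equal(shifted$tau[-1], mod$tau[-1])

  cfg0 <- perturbation_config(shift_multiplier = 0, seed = 1)
  expect_equal(perturb_node(mod, "b", cfg0)$tau, mod$tau)

  flat <- ising_model(c(a = 1, b = 1), matrix(0, 2, 2))
  expect_warning(p <- perturb_node(flat, "a", cfg), "zero SD")
  expect_equal(p$tau, flat$tau)

  half <- ising_model(c(a = 1, b = 0.5, c = 0), matrix(0, 3, 3))
  cfgabs <- perturbation_config(seed = 1, absolute_shift = 1)
  expect_equal(unname(perturb_node(half, "a", cfgabs)$tau["a"]), 0)
  expect_error(perturb_node(mod, "zz", cfg), "unknown node")
})

test_that("the benefit index has its independence closed form and two-node symmetry", {
  tau <- c(a = 0.8, b = -0.3, c = 0.1, d = -1)
  mod <- ising_model(tau, matrix(0, 4, 4))
  cfg <- perturbation_config(seed = 2)
  bi <- benefit_index(mod, cfg, "exact")
  shift <- 2 * sd(tau)
  expect_equal(bi$bi_raw, unname(plogis(tau) - plogis(tau - shift)),
               tolerance = 1e-12)

  sym <- ising_model(c(x = 0.5, y = 0.5),
                     matrix(c(0, 1, 1, 0), 2), nodes = c("x", "y"))
  bis <- benefit_index(sym, perturbation_config(seed = 2, absolute_shift = 1),
                       "exact")
  expect_equal(bis$bi_raw[1], bis$bi_raw[2], tolerance = 1e-12)
})

test_that("deactivating a node never increases its own activation probability", {
  set.seed(3)
  for (r in 1:5) {
    p <- 6
    B <- matrix(0, p, p)
    idx <- which(upper.tri(B))
    picked <- sample(idx, 5)
    B[picked] <- runif(5, -1.5, 1.5)
    B <- B + t(B)
    mod <- ising_model(rnorm(p, 0, 1), B)
    cfg <- perturbation_config(seed = r)
    base_p <- ising_expectation(mod, "exact")$p
    for (i in seq_len(p)) {
      pert_p <- ising_expectation(perturb_node(mod, i, cfg), "exact")$p
      expect_lte(pert_p[i], base_p[i] + 1e-12)
    }
  }
})

test_that("exact and Gibbs benefit indices agree within Monte-Carlo error", {
  mod <- chain_ising(8, beta = 1, tau = seq(-1.6, -0.4, length.out = 8))
  cfg <- perturbation_config(reps = 20000, seed = 4)
  bi_ex <- benefit_index(mod, cfg, "exact")
  bi_gb <- benefit_index(mod, cfg, "gibbs")
  expect_lt(max(abs(bi_ex$bi_raw - bi_gb$bi_raw)), 0.08)
})

test_that("normalization maps the maximum to 1 and preserves small negatives", {
  expect_equal(normalize_benefit(c(2, 1, -0.02)), c(1, 0.5, -0.01))
  expect_equal(normalize_benefit(rep(0.3, 4)), rep(1, 4))
  expect_error(normalize_benefit(c(-0.1, 0)), "refused")

  mod <- chain_ising(5, tau = seq(-2, -1, length.out = 5))
  bi <- normalize_benefit(benefit_index(mod, perturbation_config(seed = 5),
                                        "exact"))
  expect_equal(max(bi$bi_norm), 1)
})

test_that("84% CI significance: zero shift is never significant, a strong shift always is", {
  mod <- chain_ising(4, beta = 0.8, tau = c(-1.2, -0.8, -0.6, -0.4))
  cfg0 <- perturbation_config(shift_multiplier = 0, reps = 400, batches = 25,
                              seed = 6)
  flags0 <- significance_84ci(mod, cfg0)
  expect_false(any(flags0$significant))

  strong <- ising_model(c(a = 0, b = 0), matrix(0, 2, 2), nodes = c("a", "b"))
  cfgs <- perturbation_config(absolute_shift = 4, reps = 1000, batches = 25,
                              seed = 7)
  expect_true(all(significance_84ci(strong, cfgs)$significant))

  # flags stable across two seeds on a well-separated 6-node example
  mod6 <- ising_model(c(1.5, 1, 0.5, 0, -0.5, -1), matrix(0, 6, 6))
  cfg_a <- perturbation_config(reps = 1500, batches = 25, seed = 8)
  cfg_b <- perturbation_config(reps = 1500, batches = 25, seed = 9)
  expect_identical(significance_84ci(mod6, cfg_a)$significant,
                   significance_84ci(mod6, cfg_b)$significant)
})

test_that("the worked-example zone profile matches the published counts", {
  ib <- icf_item_bank()
  th <- score_eap(ib, as.integer(!ib$impaired_example))$theta
  zp <- zone_profile(ib, th, ib$impaired_example)
  expect_equal(sum(zp$zone == "challenge" & !zp$impaired), 5)
  expect_equal(sum(zp$zone == "competency" & zp$impaired), 4)

  # theta below every difficulty: everything is a challenge
  zp_low <- zone_profile(ib, -10, ib$impaired_example)
  expect_true(all(zp_low$zone == "challenge"))
  # zone partition is exhaustive
  expect_equal(sum(table(zp$zone, zp$impaired)), nrow(ib))
})

test_that("target recommendation ranks significant benefit first, then easy items, then id", {
  prof <- data.frame(
    item = c("d540", "d470", "d435", "b130", "x999"),
    difficulty = c(-1.17, -0.13, -0.25, 0.79, -0.13),
    zone = "competency",
    impaired = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    in_main_component = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    bi_significant = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  class(prof) <- c("zone_profile", "data.frame")
  ranked <- recommend_targets(prof)
  # significant: d435 (-0.25) before d470/x999 (-0.13, tie by id);
  # non-significant d540 last despite being easiest
  expect_identical(ranked$item, c("d435", "d470", "x999", "d540"))
  expect_identical(ranked$low_leverage, c(FALSE, FALSE, TRUE, FALSE))
  empty <- recommend_targets(prof[!prof$impaired, ])
  expect_equal(nrow(empty), 0)
})
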
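test_that("qualifier dichotomization follows the 0 -> 1, 1-4 -> 0 rule", {
  raw <- matrix(c(0, 3, 1, 0, NA, 4), 2, 3,
                dimnames = list(NULL, c("b130", "d430", "d540")))
  m <- dichotomize_icf(raw)
  expect_identical(orientation(m), "function")
  expect_identical(as.integer(m[1, ]), c(1L, 0L, NA))
  expect_identical(as.integer(m[2, ]), c(0L, 1L, 0L))

  allzero <- matrix(0, 3, 4, dimnames = list(NULL, paste0("d", 1:4)))
  expect_true(all(dichotomize_icf(allzero) == 1L))

  raw[2, 1] <- 7
  expect_error(dichotomize_icf(raw), "row 2.*b130")
})

test_that("risk recoding complements non-missing cells and refuses a double flip", {
  m <- response_matrix(matrix(c(1, 0, 1, NA), 1), "function",
                       item_ids = paste0("i", 1:4))
  r <- recode_for_network(m)
  expect_identical(orientation(r), "risk")
  expect_identical(as.integer(r[1, 1:3]), c(0L, 1L, 0L))
  expect_true(is.na(r[1, 4]))
  expect_error(recode_for_network(r), "already risk-coded")
  # double complement is identity
  back <- response_matrix(1L - unclass(r)[, , drop = FALSE], "function")
  expect_identical(unname(unclass(back)[1, 1:3]), unname(unclass(m)[1, 1:3]))
})

test_that("item filter removes high-missingness and pseudo-constant items with exact proportions", {
  set.seed(1)
  n <- 100
  X <- cbind(
    good = rbinom(n, 1, 0.5),
    holey = ifelse(seq_len(n) <= 31, NA, rbinom(n, 1, 0.5)),
    rare = c(rep(0L, 4), rep(1L, 96)))
  m <- response_matrix(X, "function")
  f <- filter_items(m)
  expect_identical(colnames(f$matrix), "good")
  rep_h <- f$report[f$report$item == "holey", ]
  expect_identical(rep_h$reason, "missing")
  expect_equal(rep_h$proportion, 0.31)
  rep_r <- f$report[f$report$item == "rare", ]
  expect_identical(rep_r$reason, "pseudo-constant")
  expect_equal(rep_r$proportion, 0.04)
  # exactly 5% minority is removed (inclusive bound)
  X2 <- cbind(a = c(rep(0L, 5), rep(1L, 95)), b = rbinom(n, 1, 0.5))
  f2 <- filter_items(response_matrix(X2, "function"))
  expect_true("a" %in% f2$report$item)
  expect_error(filter_items(response_matrix(
    matrix(c(rep(0L, 99), 1L), 100, 1), "function")), "empty scale")
})

test_that("LCA EM has the K = 1 closed form, a monotone trace, and recovers planted classes", {
  set.seed(4)
  X <- matrix(rbinom(200, 1, 0.35), 50, 4)
  f1 <- fit_lca(X, 1)
  expect_equal(unname(f1$rho[, 1]), unname(colMeans(X)))
  expect_true(all(diff(f1$trace) >= -1e-8))

  # two well-separated blocks
  n <- 150; J <- 8
  z <- rep(1:2, c(90, 60))
  rho <- cbind(rep(0.92, J), rep(0.1, J))
  Xp <- sapply(seq_len(J), function(j) rbinom(n, 1, rho[j, z]))
  f2 <- fit_lca(Xp, 2, seed = 5)
  expect_true(all(diff(f2$trace) >= -1e-8))
  hi <- which.max(f2$pi)
  expect_equal(max(f2$pi), 0.6, tolerance = 0.1)
  expect_true(all(abs(sort(colMeans(f2$rho)) - c(0.1, 0.92)) < 0.1))
  expect_warning(fit_lca(matrix(c(0, 1), 2, 2), 4), "distinct response patterns")
})

test_that("MILCA imputation is the identity on complete data, seeded, and beats the majority baseline", {
  set.seed(6)
  n <- 200; J <- 10
  z <- rep(1:2, each = n / 2)
  rho <- cbind(rep(0.85, J), rep(0.2, J))
  X <- sapply(seq_len(J), function(j) rbinom(n, 1, rho[j, z]))
  m <- response_matrix(X, "function")
  model0 <- fit_lca(m, 2, seed = 1)
  expect_identical(milca_impute(m, model0, seed = 2), m)

  holey <- inject_missingness(m, 0.1, seed = 3)
  model <- fit_lca(holey, 2, seed = 4)
  imp1 <- milca_impute(holey, model, seed = 5)
  expect_identical(imp1, milca_impute(holey, model, seed = 5))
  expect_false(anyNA(imp1))
  mask <- attr(holey, "miss_mask")
  truth <- attr(holey, "truth")
  acc <- mean(imp1[mask] == truth[mask])
  # majority-class baseline: impute every hole with the overall modal value
  baseline <- mean(truth[mask] == as.integer(mean(m) >= 0.5))
  expect_gt(acc, baseline)

  imps <- milca_impute(holey, model, seed = 6, m_imputations = 3)
  expect_length(imps, 3)
})

test_that("response matrix round-trips through its delimited text format", {
  m <- inject_missingness(generate_irt_responses(toy_bank(5),
                                                 sim_config(20, seed = 1)),
                          0.15, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_responses(m, f)
  m2 <- read_responses(f)
  expect_identical(unclass(m)[, ], unclass(m2)[, ])
  expect_identical(orientation(m2), orientation(m))
  unlink(f)
})
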
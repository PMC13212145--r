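#' Simulation settings for synthetic cohorts
#'
#' Bundles the knobs of the synthetic-data generators.  Defaults emulate the
#' study design the package targets: a cohort of 300 cancer inpatients whose
#' latent nutrition-associated health level theta is standard normal on the
#' logit scale.
#'
#' @param n_persons cohort size (default 300).
#' @param theta_mean,theta_sd latent-trait distribution (default N(0, 1)).
#' @param seed integer RNG seed.
#' @param missing_rate_per_item MCAR missingness proportion per item in
#'   \[0, 0.3) by default, so that imputation rather than item removal is the
#'   downstream path; values up to 1 are refused.
#' @param criterion_noise_sd SD of the noise added to the surrogate
#'   criterion scores, on the standardized-theta scale (default 1, giving
#'   validity correlations around 0.7).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 300, theta_mean = 0, theta_sd = 1,
                       seed = 1L, missing_rate_per_item = 0,
                       criterion_noise_sd = 1) {
  stopifnot(n_persons >= 1, theta_sd > 0,
            missing_rate_per_item >= 0, missing_rate_per_item < 1,
            criterion_noise_sd >= 0)
  structure(list(n_persons = as.integer(n_persons), theta_mean = theta_mean,
                 theta_sd = theta_sd, seed = seed,
                 missing_rate_per_item = missing_rate_per_item,
                 criterion_noise_sd = criterion_noise_sd),
            class = "sim_config")
}

#' Simulate dichotomous responses from an IRT item bank
#'
#' Forward model of the calibrated scale: each person draws a latent trait
#' from the configured normal distribution and answers every item with the
#' probability given by its 4PL response function.  The result is
#' function-coded (1 = unimpaired).
#'
#' @param ib an [item_bank()] with valid parameters.
#' @param config a [sim_config()].
#' @param theta optional fixed latent traits (overrides the draw).
#' @return A function-coded [response_matrix()] with attributes `theta`
#'   (the generating traits) for recovery tests.
#' @export
generate_irt_responses <- function(ib, config = sim_config(), theta = NULL) {
  validate_item_bank(ib)
  with_seed(config$seed, {
    n <- config$n_persons
    theta <- theta %||% rnorm(n, config$theta_mean, config$theta_sd)
    if (length(theta) != n) stop("theta must have length n_persons")
    P <- t(irf_matrix(ib, theta))            # persons x items
    X <- matrix(rbinom(length(P), 1L, P), nrow = n,
                dimnames = list(sprintf("p%03d", seq_len(n)), ib$icf_code))
    m <- response_matrix(X, "function")
    attr(m, "theta") <- theta
    m
  })
}

#' Inject missing-completely-at-random cells
#'
#' Sets entries missing at a fixed per-item rate and keeps the original
#' matrix as a `truth` attribute so imputation accuracy can be measured.
#'
#' @param m a [response_matrix()].
#' @param rate missingness probability per cell, in \[0, 1).
#' @param seed RNG seed.
#' @return The matrix with `NA` holes, plus attributes `truth` (the input)
#'   and `miss_mask` (logical matrix of injected holes).
#' @export
inject_missingness <- function(m, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  m <- as_response_matrix(m)
  if (rate == 0) return(m)
  with_seed(seed, {
    mask <- matrix(runif(length(m)) < rate, nrow = nrow(m))
    out <- unclass_rm(m)
    truth <- out
    out[mask] <- NA
    out <- response_matrix(out, orientation(m))
    attr(out, "truth") <- truth
    attr(out, "miss_mask") <- mask
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates IRT responses, a covariate table with the marginals of the
#' emulated 300-patient cohort (43% female; 62% under 70; 64% operated; 47%
#' malnourished by consensus criteria), and three surrogate criterion scores
#' that stand in for external nutrition instruments: an "MNA-like" score
#' increasing in theta and "PG-SGA-like" / "NRS-like" scores decreasing in
#' theta, each a linear transform of standardized theta plus N(0,
#' `criterion_noise_sd`) noise.
#'
#' @param config a [sim_config()].
#' @param ib item bank to simulate from (default the packaged 43-item bank).
#' @param prop_female,prop_younger,prop_operated,prop_malnourished covariate
#'   marginals.
#' @return A list of class `synthetic_cohort` with elements `responses`
#'   (function-coded, with missingness injected when configured),
#'   `covariates`, `criteria`, and `theta`.
#' @export
generate_cohort <- function(config = sim_config(), ib = icf_item_bank(),
                            prop_female = 0.43, prop_younger = 0.62,
                            prop_operated = 0.6367,
                            prop_malnourished = 0.47) {
  seeds <- child_seeds(config$seed, 4)
  resp <- generate_irt_responses(ib, config)
  theta <- attr(resp, "theta")
  n <- config$n_persons
  covariates <- with_seed(seeds[[2]], {
    sex <- factor(ifelse(runif(n) < prop_female, "female", "male"),
                  levels = c("female", "male"))
    younger <- runif(n) < prop_younger
    age <- ifelse(younger, round(runif(n, 40, 69)), round(runif(n, 70, 88)))
    data.frame(
      person_id = rownames(resp), sex = sex,
      age = age,
      age_group = factor(ifelse(younger, "younger", "older"),
                         levels = c("younger", "older")),
      operation = factor(ifelse(runif(n) < prop_operated, "yes", "no"),
                         levels = c("no", "yes")),
      bmi = round(rnorm(n, 22, 3.2), 1),
      malnutrition = factor(
        ifelse(runif(n) < prop_malnourished, "malnutrition", "none"),
        levels = c("malnutrition", "none")))
  })
  criteria <- with_seed(seeds[[3]], {
    z <- (theta - config$theta_mean) / config$theta_sd
    noise <- function() rnorm(n, 0, config$criterion_noise_sd)
    data.frame(
      person_id = rownames(resp),
      mna_like = 21 + 3.5 * (z + noise()),
      pgsga_like = 6 - 4 * (z + noise()),
      nrs_like = 3 - 1.2 * (z + noise()))
  })
  if (config$missing_rate_per_item > 0)
    resp <- inject_missingness(resp, config$missing_rate_per_item,
                               seed = seeds[[4]])
  structure(list(responses = resp, covariates = covariates,
                 criteria = criteria, theta = theta, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d persons, %d items, %d covariates\n",
              nrow(x$responses), ncol(x$responses),
              ncol(x$covariates) - 1L))
  invisible(x)
}
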
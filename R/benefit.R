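#' Perturbation settings for the benefit analysis
#'
#' @param shift_multiplier number of threshold SDs by which a node is
#'   deactivated (default 2).
#' @param reps Gibbs draws per Monte-Carlo batch (default 2000; at least
#'   1000 are recommended before trusting CIs).
#' @param batches independent batches for the 84% CIs (default 50; fewer
#'   than 20 triggers a warning).
#' @param seed RNG seed.
#' @param absolute_shift optional fixed shift that overrides
#'   `shift_multiplier * sd(tau)`.
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(shift_multiplier = 2, reps = 2000,
                                batches = 50, seed = 1L,
                                absolute_shift = NULL) {
  stopifnot(reps >= 1, batches >= 1, shift_multiplier >= 0)
  if (batches < 20) warning("fewer than 20 batches gives unstable CIs")
  structure(list(shift_multiplier = shift_multiplier, reps = reps,
                 batches = batches, seed = seed,
                 absolute_shift = absolute_shift),
            class = "perturbation_config")
}

perturbation_shift <- function(model, config) {
  if (!is.null(config$absolute_shift)) return(config$absolute_shift)
  sigma <- sd(model$tau)
  if (sigma == 0) {
    warning("thresholds have zero SD; perturbation leaves the model unchanged")
    return(0)
  }
  config$shift_multiplier * sigma
}

#' Deactivate one node by shifting its threshold
#'
#' Simulated intervention on an item: the node's threshold (residual) is
#' lowered by `shift_multiplier` standard deviations of the fitted
#' thresholds across nodes, making the impairment less likely while all
#' interactions stay in place.
#'
#' @param model an [ising_model()].
#' @param node node id or index.
#' @param config a [perturbation_config()].
#' @return The perturbed `ising_model`.
#' @export
perturb_node <- function(model, node, config = perturbation_config()) {
  idx <- if (is.character(node)) match(node, model$nodes) else node
  if (is.na(idx) || idx < 1 || idx > length(model$tau))
    stop("unknown node: ", node)
  model$tau[idx] <- model$tau[idx] - perturbation_shift(model, config)
  model
}

#' Benefit index of every node
#'
#' For each node i, BI_i is the drop in the expected system score (the
#' expected number of impaired items) caused by deactivating node i:
#' BI_i = E\[score | baseline\] - E\[score | perturb i\].  A positive BI
#' means the simulated intervention relieves overall impairment.  Under an
#' empty graph the BI has the closed form
#' logistic(tau_i) - logistic(tau_i - shift), which the enumeration engine
#' reproduces exactly.
#'
#' @param model an [ising_model()].
#' @param config a [perturbation_config()].
#' @param method `"exact"` (<= 20 nodes) or `"gibbs"`.
#' @return An object of class `benefit_result`: data frame with `node`,
#'   `bi_raw`, plus attributes `baseline` (expected score) and `config`.
#' @export
benefit_index <- function(model, config = perturbation_config(),
                          method = c("exact", "gibbs")) {
  method <- match.arg(method)
  p <- length(model$tau)
  seeds <- child_seeds(config$seed, p + 1)
  base <- ising_expectation(model, method, reps = config$reps,
                            seed = seeds[[1]])
  bi <- vapply(seq_len(p), function(i) {
    pert <- perturb_node(model, i, config)
    base$expected_score -
      ising_expectation(pert, method, reps = config$reps,
                        seed = seeds[[i + 1]])$expected_score
  }, 0)
  out <- data.frame(node = model$nodes, bi_raw = bi)
  attr(out, "baseline") <- base$expected_score
  attr(out, "config") <- config
  class(out) <- c("benefit_result", "data.frame")
  out
}

#' Normalize benefit indices to a unit maximum
#'
#' Divides every raw benefit index by the largest one, so the top item has
#' normalized BI exactly 1; small negative values survive normalization.
#' Refused when no raw index is positive.
#'
#' @param bi a `benefit_result` or numeric vector.
#' @return The input with a `bi_norm` column (or the normalized vector).
#' @export
normalize_benefit <- function(bi) {
  v <- if (is.data.frame(bi)) bi$bi_raw else bi
  mx <- max(v)
  if (mx <= 0)
    stop("all benefit indices are <= 0; normalization refused")
  if (is.data.frame(bi)) { bi$bi_norm <- v / mx; bi } else v / mx
}

#' 84% CI significance flags for the benefit index
#'
#' Simulates `batches` independent Gibbs batches of the baseline and of
#' each single-node perturbed model, takes the per-batch mean system
#' score, and forms 84% percentile intervals of the batch means.  A node's
#' benefit is significant when its perturbed interval does not overlap the
#' baseline interval (the 84%-CI overlap rule for alpha = 0.05).
#'
#' @param model an [ising_model()].
#' @param config a [perturbation_config()].
#' @return A data frame: `node`, `base_low`, `base_high`, `pert_low`,
#'   `pert_high`, `significant`.
#' @export
significance_84ci <- function(model, config = perturbation_config()) {
  p <- length(model$tau)
  nb <- config$batches
  seeds <- child_seeds(config$seed, (p + 1) * nb)
  batch_means <- function(mod, offset) {
    vapply(seq_len(nb), function(b)
      ising_expectation(mod, "gibbs", reps = config$reps,
                        seed = seeds[[offset + b]])$expected_score, 0)
  }
  ci <- function(x) quantile(x, c(0.08, 0.92), names = FALSE)
  base_ci <- ci(batch_means(model, 0))
  rows <- lapply(seq_len(p), function(i) {
    pert <- perturb_node(model, i, config)
    pci <- ci(batch_means(pert, i * nb))
    data.frame(node = model$nodes[i],
               base_low = base_ci[1], base_high = base_ci[2],
               pert_low = pci[1], pert_high = pci[2],
               significant = pci[2] < base_ci[1] || pci[1] > base_ci[2])
  })
  do.call(rbind, rows)
}

#' Full benefit analysis
#'
#' Convenience wrapper: raw benefit indices, normalization, and 84%-CI
#' significance flags in one `benefit_result`.
#'
#' @inheritParams benefit_index
#' @param ci compute significance flags (slower; Gibbs only).
#' @export
benefit_analysis <- function(model, config = perturbation_config(),
                             method = c("exact", "gibbs"), ci = TRUE) {
  bi <- normalize_benefit(benefit_index(model, config, method))
  if (ci) {
    flags <- significance_84ci(model, config)
    bi$ci84_low <- flags$pert_low
    bi$ci84_high <- flags$pert_high
    bi$significant <- flags$significant
  }
  bi
}

#' @export
print.benefit_result <- function(x, ...) {
  cat(sprintf("<benefit_result> %d nodes, baseline expected score %.2f\n",
              nrow(x), attr(x, "baseline")))
  print.data.frame(x[order(-x$bi_raw), ][seq_len(min(5, nrow(x))), ],
                   digits = 3)
  invisible(x)
}

#' @export
plot.benefit_result <- function(x, ...) {
  ord <- order(x$bi_raw)
  graphics::barplot(x$bi_raw[ord], names.arg = x$node[ord], horiz = TRUE,
                    las = 1, xlab = "benefit index", ...)
  invisible(x)
}

#' Competency/challenge zone profile of one person
#'
#' Classifies every item relative to a person's trait estimate: items with
#' difficulty above theta lie in the *functional challenge zone*, items at
#' or below theta in the *functional competency zone*.  The profile
#' attaches the person's impairment flags, main-component membership and
#' benefit-index significance, which together drive
#' [recommend_targets()].
#'
#' @param ib an [item_bank()].
#' @param theta the person's trait estimate (or an `AbilityEstimate` row
#'   from [score_eap()]).
#' @param impaired logical vector of observed impairments per item.
#' @param in_main_component optional logical vector (default from the
#'   bank's `main_component` column, else all TRUE).
#' @param bi_significant optional logical vector of benefit-significance
#'   flags (default from the bank, else NA).
#' @param difficulty which difficulty to compare against theta:
#'   `"b_mc"` (default, the Monte-Carlo-adjusted value) or `"b"`.
#' @return A data frame of class `zone_profile`.
#' @export
zone_profile <- function(ib, theta, impaired,
                         in_main_component = NULL, bi_significant = NULL,
                         difficulty = c("b_mc", "b")) {
  difficulty <- match.arg(difficulty)
  if (is.data.frame(theta)) theta <- theta$theta[1]
  d <- if (difficulty == "b_mc" && !is.null(ib$b_mc)) ib$b_mc else ib$b
  stopifnot(length(impaired) == nrow(ib))
  out <- data.frame(
    item = ib$icf_code,
    difficulty = d,
    zone = ifelse(d > theta, "challenge", "competency"),
    impaired = as.logical(impaired),
    in_main_component = in_main_component %||% ib$main_component %||% TRUE,
    bi_significant = bi_significant %||% ib$bi_significant %||% NA)
  attr(out, "theta") <- theta
  attr(out, "difficulty_used") <- difficulty
  class(out) <- c("zone_profile", "data.frame")
  out
}

#' @export
print.zone_profile <- function(x, ...) {
  tab <- table(zone = x$zone, impaired = x$impaired)
  cat(sprintf("<zone_profile> theta = %.4f (%s difficulty)\n",
              attr(x, "theta"), attr(x, "difficulty_used")))
  print(tab)
  invisible(x)
}

#' Rank impaired items as intervention targets
#'
#' Impaired items are ranked with significant benefit indices first, then
#' by ascending adjusted difficulty, ties broken by item id.  Items
#' outside the main connected component are flagged `low_leverage`: their
#' deactivation cannot propagate through the network.
#'
#' @param profile a [zone_profile()].
#' @param bi optional `benefit_result` supplying the significance flags if
#'   the profile lacks them.
#' @return A data frame of ranked targets (possibly empty).
#' @export
recommend_targets <- function(profile, bi = NULL) {
  if (!is.null(bi)) {
    idx <- match(profile$item, bi$node)
    profile$bi_significant <- bi$significant[idx]
  }
  imp <- as.data.frame(profile)[profile$impaired, , drop = FALSE]
  if (!nrow(imp)) return(imp)
  sig <- ifelse(is.na(imp$bi_significant), FALSE, imp$bi_significant)
  ord <- order(-as.integer(sig), imp$difficulty, imp$item)
  out <- imp[ord, , drop = FALSE]
  out$low_leverage <- !out$in_main_component
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
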
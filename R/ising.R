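#' Ising model over risk-coded ICF items
#'
#' A pairwise binary Markov random field over x in \{0, 1\}^p with
#' P(x) proportional to exp(sum tau_i x_i + sum_{i<j} beta_ij x_i x_j).
#' Here nodes are ICF items in risk coding (1 = impaired), `tau` is the
#' node threshold ("residual", the item's autonomous impairment tendency on
#' the log-odds scale) and `beta` holds symmetric interaction weights, zero
#' where the graph has no edge.
#'
#' @param tau numeric vector of node thresholds (named or with `nodes`).
#' @param beta symmetric numeric matrix with zero diagonal.
#' @param nodes optional node names.
#' @param edge_posterior optional symmetric matrix of edge inclusion
#'   probabilities from [bsl_structure_search()].
#' @return An object of class `ising_model`.
#' @export
ising_model <- function(tau, beta, nodes = NULL, edge_posterior = NULL) {
  p <- length(tau)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == p)) stop("beta must be p x p")
  if (max(abs(beta - t(beta))) > 1e-8) stop("beta must be symmetric")
  if (any(diag(beta) != 0)) stop("beta must have zero diagonal")
  nodes <- nodes %||% names(tau) %||% paste0("x", seq_len(p))
  names(tau) <- nodes
  dimnames(beta) <- list(nodes, nodes)
  if (!is.null(edge_posterior)) {
    if (any(edge_posterior < 0 | edge_posterior > 1))
      stop("edge posteriors must lie in [0, 1]")
    dimnames(edge_posterior) <- list(nodes, nodes)
  }
  structure(list(tau = tau, beta = beta, nodes = nodes,
                 edge_posterior = edge_posterior),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  ne <- sum(x$beta[upper.tri(x$beta)] != 0)
  cat(sprintf("<ising_model> %d nodes, %d edges\n", length(x$tau), ne))
  invisible(x)
}

# All 2^p states (rows) for exact enumeration; p guarded by callers.
ising_states <- function(p) {
  as.matrix(expand.grid(rep(list(0:1), p)))[, p:1, drop = FALSE]
}

ising_exact_probs <- function(model) {
  p <- length(model$tau)
  if (p > 20) stop("exact enumeration limited to 20 nodes")
  S <- ising_states(p)
  loge <- S %*% model$tau + rowSums((S %*% model$beta) * S) / 2
  w <- exp(loge - max(loge))
  list(states = S, probs = as.numeric(w / sum(w)))
}

#' Sample binary fields from an Ising model
#'
#' `method = "exact"` enumerates all 2^p states (p <= 20) and samples rows
#' from the exact Boltzmann distribution; `method = "gibbs"` runs a
#' single-chain Gibbs sampler (compiled) with systematic node updates,
#' 1000-sweep burn-in and thinning 10 by default.
#'
#' @param model an [ising_model()].
#' @param n number of draws.
#' @param method `"gibbs"` or `"exact"`.
#' @param seed RNG seed.
#' @param burn_in,thin Gibbs tuning.
#' @return A risk-coded [response_matrix()] of `n` draws.
#' @export
generate_ising_sample <- function(model, n, method = c("gibbs", "exact"),
                                  seed = 1L, burn_in = 1000, thin = 10) {
  method <- match.arg(method)
  p <- length(model$tau)
  X <- with_seed(seed, {
    if (method == "exact") {
      if (p > 20) stop("exact sampling limited to 20 nodes")
      ex <- ising_exact_probs(model)
      idx <- sample.int(nrow(ex$states), n, replace = TRUE, prob = ex$probs)
      ex$states[idx, , drop = FALSE]
    } else {
      init <- rbinom(p, 1L, 0.5)
      .gibbs_ising(model$tau, model$beta, as.integer(n),
                   as.integer(burn_in), as.integer(thin), init)
    }
  })
  colnames(X) <- model$nodes
  response_matrix(X, "risk")
}

#' Node activation probabilities and expected system score
#'
#' The expected system score is the expected number of active (impaired)
#' nodes, sum_i P(x_i = 1), computed either by exact enumeration of the
#' Boltzmann distribution (p <= 20) or by Gibbs Monte Carlo with a
#' batch-means standard error.
#'
#' @param model an [ising_model()].
#' @param method `"exact"` or `"gibbs"`.
#' @param reps Monte-Carlo draws for `"gibbs"`.
#' @param seed,burn_in,thin sampler settings.
#' @return A list with `p` (per-node activation probabilities),
#'   `expected_score`, and for Gibbs `mc_se` of the expected score.
#' @export
ising_expectation <- function(model, method = c("exact", "gibbs"),
                              reps = 10000, seed = 1L, burn_in = 1000,
                              thin = 1) {
  method <- match.arg(method)
  if (method == "exact") {
    ex <- ising_exact_probs(model)
    pr <- as.numeric(crossprod(ex$states, ex$probs))
    names(pr) <- model$nodes
    list(p = pr, expected_score = sum(pr), mc_se = 0)
  } else {
    X <- generate_ising_sample(model, reps, "gibbs", seed = seed,
                               burn_in = burn_in, thin = thin)
    pr <- colMeans(X)
    scores <- rowSums(X)
    nb <- max(10L, min(50L, reps %/% 20L))
    bm <- tapply(scores, cut(seq_along(scores), nb), mean)
    list(p = pr, expected_score = mean(scores),
         mc_se = sd(bm) / sqrt(length(bm)))
  }
}
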
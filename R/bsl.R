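# Laplace-approximated log marginal likelihood of one node's logistic
# regression on its neighbours, under independent N(0, prior_sd^2)
# coefficient priors.  The sum of these over nodes is the marginal
# pseudo-likelihood score of a graph.
node_log_marginal <- function(y, Z, prior_sd = 2) {
  d <- ncol(Z)
  prec <- 1 / prior_sd^2
  beta <- rep(0, d)
  for (it in 1:25) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Z, y - mu) - prec * beta
    H <- crossprod(Z * w, Z) + diag(prec, d)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(Z %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  lp <- sum(dnorm(beta, 0, prior_sd, log = TRUE))
  mu <- plogis(eta)
  H <- crossprod(Z * pmax(mu * (1 - mu), 1e-10), Z) + diag(prec, d)
  ll + lp + d / 2 * log(2 * pi) - 0.5 * determinant(H)$modulus[1]
}

#' Bayesian structure learning of the item network
#'
#' Metropolis-Hastings search over undirected graphs on the items of a
#' risk-coded binary matrix.  A graph is scored by its marginal
#' pseudo-likelihood: for each node, the marginal likelihood of a logistic
#' regression of that node on its neighbours, integrated by Laplace
#' approximation under weak normal coefficient priors, with a uniform prior
#' over graphs.  Proposals toggle one edge; edge posterior probabilities
#' are the post-burn-in visit frequencies and the MPP graph is the
#' highest-scoring structure visited.
#'
#' @param m a complete risk-coded [response_matrix()] with at most 64
#'   items.
#' @param iterations MCMC iterations (default 50000; fewer than 1000
#'   triggers a warning).
#' @param burn_in iterations discarded before accumulating edge
#'   frequencies (default `iterations/10`).
#' @param seed RNG seed.
#' @param prior_sd SD of the normal prior on regression coefficients
#'   (default 2).
#' @return An object of class `bsl_fit`: `edge_posterior`, `mpp`
#'   (adjacency matrix of the maximum-posterior graph), `acceptance_rate`,
#'   `score_trace`.
#' @export
bsl_structure_search <- function(m, iterations = 50000, burn_in = NULL,
                                 seed = 1L, prior_sd = 2) {
  X <- unclass_rm(as_response_matrix(m))
  if (anyNA(X) || !all(X %in% 0:1)) stop("complete binary matrix required")
  p <- ncol(X)
  if (p > 64) stop("structure search limited to 64 items")
  if (iterations < 1000) warning("fewer than 1000 iterations; posteriors will be noisy")
  burn_in <- burn_in %||% max(iterations %/% 10L, 1L)
  nodes <- colnames(X)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  score_node <- function(i, nbrs) {
    key <- paste0(i, "|", paste(nbrs, collapse = ","))
    val <- cache[[key]]
    if (!is.null(val)) return(val)
    Z <- cbind(1, X[, nbrs, drop = FALSE])
    val <- node_log_marginal(X[, i], Z, prior_sd)
    cache[[key]] <- val
    val
  }
  with_seed(seed, {
    adj <- matrix(FALSE, p, p)
    node_scores <- vapply(seq_len(p), function(i) score_node(i, integer(0)), 0)
    score <- sum(node_scores)
    best <- list(adj = adj, score = score)
    freq <- matrix(0, p, p)
    kept <- 0L
    acc <- 0L
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    pick <- sample.int(nrow(pairs), iterations, replace = TRUE)
    for (it in seq_len(iterations)) {
      i <- pairs[pick[it], 1]; j <- pairs[pick[it], 2]
      adj[i, j] <- adj[j, i] <- !adj[i, j]
      si <- score_node(i, which(adj[i, ]))
      sj <- score_node(j, which(adj[j, ]))
      delta <- (si - node_scores[i]) + (sj - node_scores[j])
      if (log(runif(1)) < delta) {
        node_scores[i] <- si; node_scores[j] <- sj
        score <- score + delta
        acc <- acc + 1L
        if (score > best$score) best <- list(adj = adj, score = score)
      } else {
        adj[i, j] <- adj[j, i] <- !adj[i, j]
      }
      if (it > burn_in) { freq <- freq + adj; kept <- kept + 1L }
    }
    edge_posterior <- freq / max(kept, 1L)
    dimnames(edge_posterior) <- list(nodes, nodes)
    mpp <- best$adj
    dimnames(mpp) <- list(nodes, nodes)
    structure(list(edge_posterior = edge_posterior, mpp = mpp,
                   mpp_score = best$score, acceptance_rate = acc / iterations,
                   iterations = iterations, burn_in = burn_in),
              class = "bsl_fit")
  })
}

#' @export
print.bsl_fit <- function(x, ...) {
  cat(sprintf("<bsl_fit> %d nodes, %d MPP edges, acceptance %.2f\n",
              ncol(x$edge_posterior), sum(x$mpp[upper.tri(x$mpp)]),
              x$acceptance_rate))
  invisible(x)
}

#' Threshold edge posteriors into a graph
#'
#' An edge is kept iff its posterior inclusion probability strictly
#' exceeds `cut` (default 0.5); a posterior of exactly 0.5 is dropped.
#'
#' @param edge_posterior symmetric posterior matrix (or a `bsl_fit`).
#' @param cut retention threshold.
#' @return A logical adjacency matrix.
#' @export
select_graph <- function(edge_posterior, cut = 0.5) {
  if (inherits(edge_posterior, "bsl_fit"))
    edge_posterior <- edge_posterior$edge_posterior
  adj <- edge_posterior > cut
  diag(adj) <- FALSE
  adj
}

#' Estimate Ising parameters on a fixed graph
#'
#' Maximum pseudo-likelihood: each node's threshold and interaction
#' weights come from a logistic regression of the node on its graph
#' neighbours; the interaction matrix is symmetrized by averaging the two
#' directed estimates.  A node with no neighbours gets the closed-form
#' marginal logit.  Separation (divergent coefficients) falls back to a
#' ridge-penalized fit with penalty 0.1 and is flagged.
#'
#' @param m a complete risk-coded [response_matrix()].
#' @param graph logical adjacency matrix from [select_graph()].
#' @param ridge fallback penalty (default 0.1).
#' @return An [ising_model()] with a `ridge_nodes` attribute naming nodes
#'   that needed the fallback.
#' @export
estimate_ising <- function(m, graph, ridge = 0.1) {
  X <- unclass_rm(as_response_matrix(m))
  p <- ncol(X)
  stopifnot(all(dim(graph) == p))
  nodes <- colnames(X)
  tau <- numeric(p)
  Bdir <- matrix(0, p, p)
  ridge_nodes <- character(0)
  for (i in seq_len(p)) {
    nbrs <- which(graph[i, ])
    y <- X[, i]
    if (!length(nbrs)) {
      ph <- mean(y)
      ph <- min(max(ph, 1e-6), 1 - 1e-6)
      tau[i] <- qlogis(ph)
      next
    }
    Z <- cbind(1, X[, nbrs, drop = FALSE])
    fit <- suppressWarnings(glm.fit(Z, y, family = binomial()))
    cf <- fit$coefficients
    if (!fit$converged || any(!is.finite(cf)) || any(abs(cf) > 15)) {
      cf <- ridge_logistic(y, Z, ridge)
      ridge_nodes <- c(ridge_nodes, nodes[i])
    }
    tau[i] <- cf[1]
    Bdir[i, nbrs] <- cf[-1]
  }
  beta <- (Bdir + t(Bdir)) / 2
  beta[!graph] <- 0
  diag(beta) <- 0
  model <- ising_model(tau, beta, nodes = nodes)
  attr(model, "ridge_nodes") <- ridge_nodes
  model
}

# Logistic regression with an L2 penalty on all coefficients except the
# intercept; Newton iterations.
ridge_logistic <- function(y, Z, lambda) {
  d <- ncol(Z)
  pen <- diag(c(0, rep(lambda, d - 1)), d)
  beta <- rep(0, d)
  for (it in 1:50) {
    mu <- plogis(drop(Z %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Z, y - mu) - pen %*% beta
    H <- crossprod(Z * w, Z) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  drop(beta)
}

#' Largest connected component of an item graph
#'
#' Returns the node set of the largest connected component; ties on size
#' are broken by taking the lexicographically smallest sorted node set.
#' An empty graph yields the single node with the smallest id.
#'
#' @param graph logical adjacency matrix (dimnames = node ids).
#' @return Character vector of node ids.
#' @export
maximal_connected_component <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph != 0, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  sets <- lapply(cand, function(k)
    sort(names(comp$membership)[comp$membership == k]))
  sets[[order(vapply(sets, `[`, "", 1))[1]]]
}

#' Export an Ising network
#'
#' Writes the retained edges as a delimited edge list (`node_i`, `node_j`,
#' `beta`, `posterior`) and optionally as GraphML with node attributes.
#'
#' @param model an [ising_model()].
#' @param file path for the edge list (TSV).
#' @param graphml optional path for a GraphML export.
#' @param node_attrs optional data frame of per-node attributes (rows in
#'   node order).
#' @return `file`, invisibly.
#' @export
export_network <- function(model, file, graphml = NULL, node_attrs = NULL) {
  idx <- which(model$beta != 0 & upper.tri(model$beta), arr.ind = TRUE)
  el <- data.frame(node_i = model$nodes[idx[, 1]],
                   node_j = model$nodes[idx[, 2]],
                   beta = model$beta[idx],
                   posterior = if (is.null(model$edge_posterior)) NA
                               else model$edge_posterior[idx])
  write.table(el, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_adjacency_matrix(
      abs(model$beta), mode = "undirected", weighted = TRUE)
    igraph::V(g)$tau <- unname(model$tau)
    if (!is.null(node_attrs))
      for (nm in names(node_attrs))
        g <- igraph::set_vertex_attr(g, nm, value = node_attrs[[nm]])
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(file)
}
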
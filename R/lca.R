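#' Latent class analysis of binary responses by EM
#'
#' Fits an unrestricted latent class model with `K` classes to a binary
#' matrix: mixing weights pi_k and class-conditional response probabilities
#' rho_jk, assuming local independence within class.  Missing entries are
#' handled by marginalizing their likelihood contribution, which is what
#' makes the model usable for imputation ([milca_impute()]).  The EM
#' log-likelihood is non-decreasing across iterations.
#'
#' @param m a [response_matrix()] or 0/1 matrix, possibly with `NA`.
#' @param K number of classes (>= 1).
#' @param seed RNG seed for the random start.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence threshold.
#' @param n_starts random restarts; the best log-likelihood wins.
#' @return An object of class `lca_fit`: `pi` (K), `rho` (items x K),
#'   `posterior` (persons x K), `logLik`, `trace`, `K`, `npar`, `bic`.
#' @export
fit_lca <- function(m, K, seed = 1L, max_iter = 500, tol = 1e-8,
                    n_starts = 3) {
  X <- unclass_rm(as_response_matrix(m))
  n <- nrow(X); J <- ncol(X)
  stopifnot(K >= 1)
  pat <- apply(X, 1, paste, collapse = ",")
  if (K > length(unique(pat))) {
    warning("K exceeds the number of distinct response patterns; ",
            "degenerate classes possible")
    n_starts <- 1
  }
  obs <- !is.na(X); X0 <- ifelse(obs, X, 0)
  run_em <- function() {
    rho <- matrix(runif(J * K, 0.2, 0.8), J, K)
    if (K == 1) rho <- matrix(colSums(X0) / pmax(colSums(obs), 1), J, 1)
    pi_k <- rep(1 / K, K)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      lr <- log(pmin(pmax(rho, 1e-12), 1 - 1e-12))
      lq <- log1p(-pmin(pmax(rho, 1e-12), 1 - 1e-12))
      LL <- X0 %*% lr + (obs - X0) %*% lq            # persons x K
      LL <- sweep(LL, 2, log(pi_k), "+")
      mx <- apply(LL, 1, max)
      A <- exp(LL - mx)
      ll <- sum(mx + log(rowSums(A)))
      trace <- c(trace, ll)
      z <- A / rowSums(A)
      pi_k <- pmax(colMeans(z), 1e-12); pi_k <- pi_k / sum(pi_k)
      rho <- (crossprod(X0, z)) / pmax(crossprod(obs, z), 1e-12)
      if (it > 1 && abs(trace[it] - trace[it - 1]) <
            tol * (abs(trace[it - 1]) + 1e-3)) break
    }
    list(pi = pi_k, rho = rho, posterior = z, logLik = ll, trace = trace)
  }
  seeds <- child_seeds(seed, n_starts)
  fits <- lapply(seeds, function(s) with_seed(s, run_em()))
  best <- fits[[which.max(vapply(fits, `[[`, 0, "logLik"))]]
  npar <- (K - 1) + J * K
  rownames(best$rho) <- colnames(X)
  structure(c(best, list(K = K, n = n, npar = npar,
                         bic = -2 * best$logLik + npar * log(n))),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca_fit> K = %d, logLik = %.2f, BIC = %.2f\n",
              x$K, x$logLik, x$bic))
  invisible(x)
}

#' @export
logLik.lca_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' Choose the latent class count by BIC
#'
#' Fits [fit_lca()] over a range of K and returns the fit with the lowest
#' BIC, with the comparison table attached.
#'
#' @inheritParams fit_lca
#' @param K_range candidate class counts (default 1:6).
#' @return The winning `lca_fit`, with a `bic_table` attribute.
#' @export
select_lca_k <- function(m, K_range = 1:6, seed = 1L, ...) {
  seeds <- child_seeds(seed, length(K_range))
  fits <- mapply(function(K, s) fit_lca(m, K, seed = s, ...),
                 K_range, seeds, SIMPLIFY = FALSE)
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- fits[[which.min(bics)]]
  attr(best, "bic_table") <- data.frame(K = K_range, bic = bics)
  best
}

#' MILCA: multiple imputation based on latent class analysis
#'
#' Draws every missing cell from its posterior predictive distribution
#' under a fitted latent class model: a class is drawn from the person's
#' posterior given the observed entries, then the cell from that class's
#' response probability.  A person with no observed entries is imputed from
#' the marginal class mixture (and flagged in the `all_missing` attribute).
#'
#' @param m the incomplete [response_matrix()] the model was fitted on.
#' @param model an [lca_fit()] on the same items.
#' @param seed RNG seed.
#' @param m_imputations number of completed datasets (default 1; the
#'   downstream stages consume a single matrix).
#' @return A completed `response_matrix` (or a list of them when
#'   `m_imputations > 1`).
#' @export
milca_impute <- function(m, model, seed = 1L, m_imputations = 1) {
  m <- as_response_matrix(m)
  X <- unclass_rm(m)
  if (!identical(rownames(model$rho), colnames(X)))
    stop("model was not fitted on these items")
  if (!anyNA(X) && m_imputations == 1) return(m)
  all_missing <- rowSums(!is.na(X)) == 0
  one <- function() {
    out <- X
    cls <- vapply(seq_len(nrow(X)), function(i) {
      pr <- if (all_missing[i]) model$pi else model$posterior[i, ]
      sample.int(model$K, 1, prob = pr)
    }, 0L)
    for (i in seq_len(nrow(X))) {
      mis <- which(is.na(X[i, ]))
      if (length(mis))
        out[i, mis] <- rbinom(length(mis), 1L, model$rho[mis, cls[i]])
    }
    res <- response_matrix(out, orientation(m), rownames(X), colnames(X))
    attr(res, "all_missing") <- rownames(X)[all_missing]
    res
  }
  imps <- with_seed(seed, lapply(seq_len(m_imputations), function(i) one()))
  if (m_imputations == 1) imps[[1]] else imps
}

#' Latent class reliability coefficient (LCRC)
#'
#' Reliability of the total score implied by a latent class model: the
#' between-class variance of the class true scores t_k = sum_j rho_jk over
#' the total variance (between-class plus the local-independence
#' within-class variance sum_j rho_jk (1 - rho_jk)).
#'
#' @param model an [lca_fit()].
#' @return A number in \[0, 1\].
#' @export
lcrc <- function(model) {
  t_k <- colSums(model$rho)
  v_between <- sum(model$pi * t_k^2) - sum(model$pi * t_k)^2
  v_within <- sum(model$pi * colSums(model$rho * (1 - model$rho)))
  if (v_between + v_within == 0) stop("degenerate model: zero total variance")
  v_between / (v_between + v_within)
}
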
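#' Four-parameter logistic item response function
#'
#' P(X = 1 | theta) = g + (u - g) / (1 + exp(-a (theta - b))).  No 1.7
#' scaling constant is applied, so `a` is on the logistic metric.
#'
#' @param theta latent trait value(s), logit scale.
#' @param a discrimination (> 0).
#' @param b difficulty.
#' @param g lower asymptote in \[0, 1).
#' @param u upper asymptote in (g, 1\].
#' @return Response probabilities in \[g, u\], vectorized over `theta`.
#' @examples
#' irf_probability(1.04, a = 5.59, b = 1.04)  # 0.5 at theta = b when g = 0
#' @export
irf_probability <- function(theta, a, b, g = 0, u = 1) {
  if (any(a <= 0)) stop("discrimination a must be > 0")
  if (any(g < 0 | g >= 1) || any(u <= g | u > 1))
    stop("asymptotes must satisfy 0 <= g < u <= 1")
  g + (u - g) * plogis(a * (theta - b))
}

# Items x quadrature probability matrix for an item bank.
irf_matrix <- function(ib, theta) {
  t(vapply(seq_len(nrow(ib)), function(j)
    irf_probability(theta, ib$a[j], ib$b[j], ib$g[j], ib$u[j]),
    numeric(length(theta))))
}

# Fixed quadrature over a standard-normal (or shifted) prior.
quad_grid <- function(n_quad = 61, range = c(-6, 6), mean = 0, sd = 1) {
  nodes <- seq(range[1], range[2], length.out = n_quad)
  w <- dnorm(nodes, mean, sd)
  list(nodes = nodes, weights = w / sum(w))
}

# Clamp probabilities away from 0/1 so saturated items (very large a)
# cannot produce 0 * -Inf in the likelihood.
clamp_prob <- function(P, eps = 1e-12) pmin(pmax(P, eps), 1 - eps)

#' Fit a logistic IRT model by marginal maximum likelihood (EM)
#'
#' Estimates item parameters of the 1PL, 2PL, 3PL or 4PL model by the
#' Bock-Aitkin EM algorithm with fixed quadrature over a standard-normal
#' latent-trait prior.  The E step computes each person's posterior over the
#' quadrature nodes; the M step maximizes every item's expected binomial
#' log-likelihood by box-constrained quasi-Newton steps.  The observed-data
#' marginal log-likelihood is non-decreasing across cycles (up to quadrature
#' round-off) and is tracked in `$trace`.
#'
#' Bounds used for stabilization: `a` in \[0.05, 100\] (the cap keeps the
#' arithmetic finite when an item approaches a step function), `b` in the
#' quadrature range, `g` in \[0, 0.5\], `u` in \[0.5, 1\].  An optional weak
#' logit-normal prior on `g` can be enabled with `g_prior_sd` (off by
#' default).
#'
#' @param m a function-coded [response_matrix()] or plain 0/1 matrix
#'   (missing entries are skipped in the likelihood).
#' @param model `"1PL"`, `"2PL"`, `"3PL"` or `"4PL"`.
#' @param n_quad,range quadrature size and support; defaults 61 points on
#'   \[-6, 6\].
#' @param tol convergence threshold on the maximum absolute parameter change
#'   (default 1e-5).
#' @param max_cycles EM cycle cap; non-convergence returns the last iterate
#'   with a warning and `converged = FALSE`.
#' @param g_prior_sd optional SD of a weak N(qlogis(0.1), sd) prior on
#'   logit(g); `NULL` (default) fits g unpenalized.
#' @param start optional [item_bank()] of starting values (used by the
#'   parametric bootstrap to warm-start replicate refits).
#' @return An object of class `irt_fit` with elements `item_bank`, `logLik`,
#'   `model`, `npar`, `n`, `trace`, `converged`, `quad`, and per-item
#'   `inestimable` flags for items answered identically by everyone.
#' @seealso [score_eap()], [compare_models()], [item_fit()],
#'   [monte_carlo_difficulty()]
#' @export
fit_irt <- function(m, model = c("3PL", "1PL", "2PL", "4PL"),
                    n_quad = 61, range = c(-6, 6), tol = 1e-5,
                    max_cycles = 500, g_prior_sd = NULL, start = NULL) {
  model <- match.arg(model)
  X <- unclass_rm(as_response_matrix(m))
  if (is_response_matrix(m) && orientation(m) == "risk")
    stop("fit_irt expects function-coded responses")
  n <- nrow(X); J <- ncol(X)
  if (J < 2) stop("need at least 2 items")
  q <- quad_grid(n_quad, range)
  obs <- !is.na(X)
  pbar <- colSums(X * obs, na.rm = TRUE) / colSums(obs)
  inest <- pbar %in% c(0, 1)
  if (any(inest))
    warning("items answered identically by all persons flagged inestimable: ",
            paste(colnames(X)[inest], collapse = ", "))
  # starting values
  p0 <- pmin(pmax(pbar, 0.02), 0.98)
  par <- data.frame(a = rep(1, J), b = -qlogis(p0),
                    g = if (model %in% c("3PL", "4PL")) rep(0.05, J) else rep(0, J),
                    u = if (model == "4PL") rep(0.98, J) else rep(1, J))
  if (!is.null(start)) {
    par$a <- pmin(pmax(start$a, 0.05), 100)
    par$b <- pmin(pmax(start$b, range[1]), range[2])
    if (model %in% c("3PL", "4PL")) par$g <- pmin(start$g, 0.5)
    if (model == "4PL") par$u <- pmax(start$u, 0.5)
  }
  free <- switch(model,
    "1PL" = c(a = TRUE, b = TRUE, g = FALSE, u = FALSE),
    "2PL" = c(a = TRUE, b = TRUE, g = FALSE, u = FALSE),
    "3PL" = c(a = TRUE, b = TRUE, g = TRUE, u = FALSE),
    "4PL" = c(a = TRUE, b = TRUE, g = TRUE, u = TRUE))
  lower <- c(a = 0.05, b = range[1], g = 0, u = 0.5)
  upper <- c(a = 100, b = range[2], g = 0.5, u = 1)
  g_pen <- function(g) {
    if (is.null(g_prior_sd) || g <= 0) return(0)
    -dnorm(qlogis(pmax(g, 1e-6)), qlogis(0.1), g_prior_sd, log = TRUE)
  }
  nodes <- q$nodes
  item_obj <- function(pv, r, nq) {
    s <- plogis(pv[1] * (nodes - pv[2]))
    P <- pmin(pmax(pv[3] + (pv[4] - pv[3]) * s, 1e-10), 1 - 1e-10)
    -(sum(r * log(P) + (nq - r) * log1p(-P))) + g_pen(pv[3])
  }
  # analytic gradient of the expected negative log-likelihood (the weak
  # g prior, when enabled, is handled by finite differences on g only)
  item_grad <- function(pv, r, nq, idx) {
    s <- plogis(pv[1] * (nodes - pv[2]))
    P <- pmin(pmax(pv[3] + (pv[4] - pv[3]) * s, 1e-10), 1 - 1e-10)
    w <- r / P - (nq - r) / (1 - P)
    ds <- (pv[4] - pv[3]) * s * (1 - s)
    gfull <- c(a = -sum(w * ds * (nodes - pv[2])),
               b = sum(w * ds * pv[1]),
               g = -sum(w * (1 - s)),
               u = -sum(w * s))
    if (!is.null(g_prior_sd)) {
      eps <- 1e-6
      hi <- min(pv[3] + eps, 0.5); lo <- max(pv[3] - eps, 1e-8)
      gfull["g"] <- gfull["g"] + (g_pen(hi) - g_pen(lo)) / (hi - lo)
    }
    gfull[idx]
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  X0 <- ifelse(obs, X, 0L)
  for (cycle in seq_len(max_cycles)) {
    ib <- item_bank(colnames(X), par$a, par$b, par$g, par$u)
    P <- clamp_prob(irf_matrix(ib, q$nodes))
    LL <- X0 %*% log(P) + (obs - X0) %*% log1p(-P)   # persons x quad
    mx <- apply(LL, 1, max)
    A <- exp(LL - mx) * rep(q$weights, each = n)
    marg <- rowSums(A)
    ll <- sum(mx + log(marg))
    trace <- c(trace, ll)
    post <- A / marg
    # expected counts; missing responses contribute to neither r nor nq
    r <- t(X0) %*% post                      # items x quad correct
    nq <- t(obs) %*% post                    # items x quad tried
    old <- unlist(par)
    if (model == "1PL") {
      a0 <- par$a[1]
      for (j in which(!inest)) {
        par$b[j] <- optimize(function(bb) item_obj(c(a0, bb, 0, 1), r[j, ], nq[j, ]),
                             lower = range[1], upper = range[2])$minimum
      }
      par$a[] <- optimize(function(aa) {
        s <- 0
        for (j in which(!inest)) s <- s + item_obj(c(aa, par$b[j], 0, 1), r[j, ], nq[j, ])
        s
      }, lower = lower["a"], upper = 20)$minimum
    } else {
      idx <- which(free)
      for (j in which(!inest)) {
        pv <- c(par$a[j], par$b[j], par$g[j], par$u[j])
        fn <- function(th) { pv[idx] <- th; item_obj(pv, r[j, ], nq[j, ]) }
        gr <- function(th) { pv[idx] <- th; item_grad(pv, r[j, ], nq[j, ], idx) }
        opt <- optim(pv[idx], fn, gr, method = "L-BFGS-B",
                     lower = lower[idx], upper = upper[idx],
                     control = list(maxit = 50))
        pv[idx] <- opt$par
        par$a[j] <- pv[1]; par$b[j] <- pv[2]; par$g[j] <- pv[3]; par$u[j] <- pv[4]
      }
    }
    if (max(abs(unlist(par) - old)) < tol && cycle > 1) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d cycles; returning last iterate",
                    max_cycles))
  ib <- item_bank(colnames(X), par$a, par$b, par$g, par$u)
  npar <- switch(model, "1PL" = J + 1, "2PL" = 2 * J, "3PL" = 3 * J,
                 "4PL" = 4 * J)
  structure(list(item_bank = ib, logLik = trace[length(trace)], model = model,
                 npar = npar, n = n, trace = trace, converged = converged,
                 inestimable = setNames(inest, colnames(X)),
                 quad = q, data = X),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("<irt_fit> %s, %d items, n = %d, logLik = %.2f (%sconverged)\n",
              x$model, nrow(x$item_bank), x$n, x$logLik,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.irt_fit <- function(object, ...) {
  as.matrix(object$item_bank[, c("a", "b", "g", "u")])
}

#' @export
logLik.irt_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
summary.irt_fit <- function(object, ...) {
  ib <- object$item_bank
  cat(sprintf("%s fit on %d persons x %d items\n", object$model, object$n,
              nrow(ib)))
  cat(sprintf("logLik %.2f, %d parameters, BIC %.2f, EM cycles %d\n",
              object$logLik, object$npar,
              -2 * object$logLik + object$npar * log(object$n),
              length(object$trace)))
  print.data.frame(as.data.frame(ib), digits = 3)
  invisible(object)
}

#' @export
predict.irt_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data else unclass_rm(as_response_matrix(newdata))
  score_eap(object$item_bank, X,
            n_quad = length(object$quad$nodes),
            range = range(object$quad$nodes))
}

#' @export
simulate.irt_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  n <- n %||% object$n
  cfg <- sim_config(n_persons = n, seed = seed)
  generate_irt_responses(object$item_bank, cfg)
}

#' @export
residuals.irt_fit <- function(object, ...) {
  th <- predict(object)$theta
  P <- t(irf_matrix(object$item_bank, th))  # persons x items
  (object$data - P) / sqrt(P * (1 - P))
}

#' Expected-a-posteriori (EAP) latent trait scores
#'
#' Posterior mean and SD of theta under a normal prior with fixed
#' quadrature, given fixed item parameters.  Missing responses are skipped
#' in the likelihood; a person with no observed responses receives the
#' (discretized) prior mean and SD.
#'
#' @param ib an [item_bank()].
#' @param responses a 0/1 vector of length `nrow(ib)`, or a persons x items
#'   matrix with columns matching the bank order.
#' @param prior_mean,prior_sd normal prior parameters (default standard
#'   normal).
#' @param n_quad,range quadrature settings (default 61 points on \[-6, 6\]).
#' @return A data frame with columns `theta`, `se` and attribute
#'   `method = "EAP"`.
#' @examples
#' ib <- icf_item_bank()
#' score_eap(ib, as.integer(!ib$impaired_example))$theta
#' @export
score_eap <- function(ib, responses, prior_mean = 0, prior_sd = 1,
                      n_quad = 61, range = c(-6, 6)) {
  if (nrow(ib) < 1) stop("empty item bank")
  X <- if (is.null(dim(responses))) matrix(responses, nrow = 1)
       else unclass_rm(as_response_matrix(responses))
  if (ncol(X) != nrow(ib))
    stop("response length does not match item bank")
  q <- quad_grid(n_quad, range, prior_mean, prior_sd)
  P <- clamp_prob(irf_matrix(ib, q$nodes))
  obs <- !is.na(X)
  X0 <- ifelse(obs, X, 0)
  LL <- X0 %*% log(P) + (obs - X0) %*% log1p(-P)
  A <- exp(LL - apply(LL, 1, max)) * rep(q$weights, each = nrow(X))
  post <- A / rowSums(A)
  theta <- drop(post %*% q$nodes)
  se <- sqrt(pmax(drop(post %*% q$nodes^2) - theta^2, 0))
  out <- data.frame(person_id = rownames(X) %||% seq_len(nrow(X)),
                    theta = theta, se = se)
  attr(out, "method") <- "EAP"
  out
}
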
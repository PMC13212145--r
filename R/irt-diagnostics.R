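#' Compare nested IRT fits by LRT and BIC
#'
#' Given fits of the nested 1PL/2PL/3PL/4PL family on the same data,
#' computes BIC = -2 logLik + k log(n) per model and likelihood-ratio
#' chi-squared tests between adjacent pairs (df = parameter-count
#' difference).  The selected model is the lowest-BIC model among those
#' passing an adequacy gate: when the data matrix is supplied, per-item
#' S-X2 p-values are Benjamini-Hochberg corrected at `gate_alpha` and a
#' model is adequate if no item is rejected; without data all models are
#' treated as adequate.
#'
#' @param fits list of `irt_fit` objects in nesting order.
#' @param m optional response matrix for the item-fit adequacy gate.
#' @param gate_alpha BH level for the gate (default 0.05).
#' @return An object of class `model_comparison`: `table` (model, logLik,
#'   npar, BIC, adequate), `lrt` (pairwise tests), `selected`.
#' @export
compare_models <- function(fits, m = NULL, gate_alpha = 0.05) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, "", "model")
  n <- unique(vapply(fits, `[[`, 0, "n"))
  if (length(n) != 1) stop("fits are not on identical data")
  ll <- vapply(fits, `[[`, 0, "logLik")
  k <- vapply(fits, `[[`, 0, "npar")
  ord <- order(k)
  fits <- fits[ord]; ll <- ll[ord]; k <- k[ord]
  bic <- -2 * ll + k * log(n)
  adequate <- rep(TRUE, length(fits))
  if (!is.null(m)) {
    adequate <- vapply(fits, function(f) {
      p_adj <- p.adjust(item_fit(f, m)$sx2_p, "BH")
      all(p_adj >= gate_alpha, na.rm = TRUE)
    }, TRUE)
  }
  lrt <- NULL
  if (length(fits) > 1) {
    i <- seq_len(length(fits) - 1)
    stat <- pmax(2 * (ll[i + 1] - ll[i]), 0)
    df <- k[i + 1] - k[i]
    if (any(df < 0)) stop("models are not properly nested")
    lrt <- data.frame(null = names(fits)[i], alt = names(fits)[i + 1],
                      statistic = stat, df = df,
                      p_value = ifelse(df > 0,
                                       pchisq(stat, df, lower.tail = FALSE),
                                       NA_real_))
  }
  pool <- if (any(adequate)) which(adequate) else seq_along(fits)
  selected <- names(fits)[pool[which.min(bic[pool])]]
  structure(list(table = data.frame(model = names(fits), logLik = ll,
                                    npar = k, BIC = bic,
                                    adequate = adequate),
                 lrt = lrt, selected = selected, n = n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print.data.frame(x$table, digits = 4)
  if (!is.null(x$lrt)) print.data.frame(x$lrt, digits = 4)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

# Lord-Wingersky recursion: distribution of the summed score at each
# quadrature node.  P is items x quad; returns (J+1) x quad.
lw_score_dist <- function(P) {
  J <- nrow(P); Q <- ncol(P)
  f <- matrix(0, J + 1, Q)
  f[1, ] <- 1
  for (j in seq_len(J)) {
    fn <- matrix(0, J + 1, Q)
    fn[1, ] <- f[1, ] * (1 - P[j, ])
    for (s in seq_len(j)) {
      fn[s + 1, ] <- f[s + 1, ] * (1 - P[j, ]) + f[s, ] * P[j, ]
    }
    f <- fn
  }
  f
}

#' Item fit: S-X2, INFIT and OUTFIT
#'
#' S-X2 compares observed and model-implied proportions correct per summed
#' score, with the implied proportions obtained from the Lord-Wingersky
#' score-distribution recursion on the remaining items; score groups are
#' collapsed from the extremes until every expected cell count is at least
#' `min_expected`.  INFIT is the information-weighted and OUTFIT the
#' unweighted mean-square standardized residual at the EAP trait estimate;
#' both are near 1 under the generating model.
#'
#' @param fit an `irt_fit`.
#' @param m the response matrix (defaults to the fitting data).
#' @param min_expected collapsing bound for the S-X2 table (default 1).
#' @return A data frame per item: `sx2`, `sx2_df`, `sx2_p`, `infit`,
#'   `outfit`.
#' @export
item_fit <- function(fit, m = NULL, min_expected = 1) {
  X <- if (is.null(m)) fit$data else unclass_rm(as_response_matrix(m))
  if (anyNA(X)) stop("complete matrix required for item fit")
  ib <- fit$item_bank
  q <- fit$quad
  P <- irf_matrix(ib, q$nodes)
  J <- nrow(P)
  n <- nrow(X)
  tot <- rowSums(X)
  # INFIT/OUTFIT from residuals integrated over each person's posterior,
  # which avoids the downward bias of plugging in shrunken EAP estimates
  Pq <- clamp_prob(P)
  LLp <- X %*% log(Pq) + (1 - X) %*% log1p(-Pq)
  A <- exp(LLp - apply(LLp, 1, max)) * rep(q$weights, each = n)
  post <- A / rowSums(A)                     # persons x quad
  EP <- post %*% t(Pq)                       # E[P_j(theta) | x_i]
  EP2 <- post %*% t(Pq^2)
  # E[(x - P)^2] and E[P(1-P)] under the posterior; for OUTFIT the
  # standardized ratio is averaged inside the posterior expectation
  R2 <- X - 2 * X * EP + EP2
  W <- EP - EP2
  EinvP <- post %*% t(1 / Pq)
  Eodds <- post %*% t(Pq / (1 - Pq))
  Z2 <- X * (EinvP - 1) + (1 - X) * Eodds
  outfit <- colMeans(Z2)
  infit <- colSums(R2) / colSums(W)
  # S-X2 per item
  full <- lw_score_dist(P)                   # (J+1) x Q
  marg_s <- as.numeric(full %*% q$weights)   # P(S = s), s = 0..J
  sx2 <- sx2_df <- sx2_p <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    rest <- lw_score_dist(P[-j, , drop = FALSE])   # J x Q for scores 0..J-1
    # E[x_j = 1 | S = s] for s = 1..J-1 (scores where both outcomes possible)
    s_seq <- 1:(J - 1)
    num <- vapply(s_seq, function(s)
      sum(q$weights * P[j, ] * rest[s, ]), 0)      # rest score s-1
    den <- marg_s[s_seq + 1]
    e1 <- ifelse(den > 0, num / den, NA)
    obs_n <- tabulate(factor(tot, levels = s_seq), nbins = length(s_seq))
    obs_1 <- vapply(s_seq, function(s) sum(X[tot == s, j]), 0)
    keep <- obs_n > 0 & !is.na(e1)
    Ecell <- cbind(obs_n * e1, obs_n * (1 - e1))[keep, , drop = FALSE]
    Ocell <- cbind(obs_1, obs_n - obs_1)[keep, , drop = FALSE]
    # collapse adjacent rows until expected counts reach min_expected
    grp <- collapse_groups(Ecell, min_expected)
    Eg <- rowsum(Ecell, grp); Og <- rowsum(Ocell, grp)
    ok <- Eg > 0
    stat <- sum((Og[ok] - Eg[ok])^2 / Eg[ok])
    npar_j <- switch(fit$model, "1PL" = 1, "2PL" = 2, "3PL" = 3, "4PL" = 4)
    dfj <- max(nrow(Eg) - npar_j, 1)
    sx2[j] <- stat; sx2_df[j] <- dfj
    sx2_p[j] <- pchisq(stat, dfj, lower.tail = FALSE)
  }
  data.frame(item = ib$icf_code, sx2 = sx2, sx2_df = sx2_df, sx2_p = sx2_p,
             infit = infit, outfit = outfit)
}

# Merge adjacent score groups (rows) until both expected columns >= bound.
collapse_groups <- function(E, bound) {
  ng <- nrow(E)
  grp <- seq_len(ng)
  if (ng == 0) return(grp)
  repeat {
    Eg <- rowsum(E, grp)
    small <- which(apply(Eg, 1, min) < bound)
    if (!length(small) || nrow(Eg) == 1) break
    ids <- sort(unique(grp))
    s <- small[1]
    # merge with the neighbouring group (towards the middle)
    target <- if (s == 1) ids[2] else ids[match(ids[s], ids) - 1]
    grp[grp == ids[s]] <- target
  }
  match(grp, sort(unique(grp)))
}

#' Scale reliability: Cronbach's alpha and the LCRC
#'
#' Cronbach's alpha from the classical formula
#' (k/(k-1)) (1 - sum item variances / total-score variance) and the
#' latent class reliability coefficient from a latent class model of the
#' same matrix ([lcrc()]); when no model is supplied one is chosen by BIC
#' over K = 1..6.
#'
#' @param m a complete binary [response_matrix()].
#' @param lca_model optional [fit_lca()] result.
#' @param seed seed for the internal LCA selection.
#' @return A list: `cronbach_alpha`, `lcrc`, `K`.
#' @export
reliability <- function(m, lca_model = NULL, seed = 1L) {
  X <- unclass_rm(as_response_matrix(m))
  if (anyNA(X)) stop("complete matrix required")
  k <- ncol(X)
  vtot <- var(rowSums(X))
  if (vtot == 0) stop("zero total-score variance; alpha undefined")
  alpha <- (k / (k - 1)) * (1 - sum(apply(X, 2, var)) / vtot)
  lca_model <- lca_model %||% select_lca_k(X, 1:6, seed = seed)
  list(cronbach_alpha = alpha, lcrc = lcrc(lca_model), K = lca_model$K)
}

#' Differential test functioning between groups
#'
#' Compares expected total-score curves T(theta) = sum_i P_i(theta) of a
#' reference and a focal parameter set over a theta grid.  With
#' `link = "mean_sigma"` the focal parameters are first placed on the
#' reference metric by mean/sigma linking of the difficulties (b* = A b +
#' B, a* = a / A); use `link = "none"` when both sets are already on a
#' common scale.  Signed DTF is the mean of T_focal - T_reference over the
#' focal trait density and unsigned DTF the mean absolute difference; both
#' are 0 for identical parameter sets.
#'
#' @param ref,focal `irt_fit` objects or `item_bank`s on the same items.
#' @param theta_grid evaluation grid (default 61 points on \[-6, 6\]).
#' @param link `"mean_sigma"` or `"none"`.
#' @param dif_cut per-item flagging bound on the unsigned expected-score
#'   difference, in probability units (default 0.1).
#' @return A list of class `dtf_report`: `sdtf`, `udtf`, `curves` (grid,
#'   reference and focal expected scores), `item_dif` with flags.
#' @export
dif_dtf <- function(ref, focal, theta_grid = seq(-6, 6, length.out = 61),
                    link = c("mean_sigma", "none"), dif_cut = 0.1) {
  link <- match.arg(link)
  ib_r <- if (inherits(ref, "irt_fit")) ref$item_bank else ref
  ib_f <- if (inherits(focal, "irt_fit")) focal$item_bank else focal
  if (!identical(ib_r$icf_code, ib_f$icf_code))
    stop("reference and focal banks must cover the same items")
  if (link == "mean_sigma") {
    A <- sd(ib_r$b) / sd(ib_f$b)
    B <- mean(ib_r$b) - A * mean(ib_f$b)
    ib_f$b <- A * ib_f$b + B
    ib_f$a <- ib_f$a / A
  }
  w <- dnorm(theta_grid); w <- w / sum(w)
  Pr <- irf_matrix(ib_r, theta_grid)
  Pf <- irf_matrix(ib_f, theta_grid)
  Tr <- colSums(Pr); Tf <- colSums(Pf)
  item_udif <- as.numeric(abs(Pf - Pr) %*% w)
  structure(list(
    sdtf = sum(w * (Tf - Tr)),
    udtf = sum(w * abs(Tf - Tr)),
    curves = data.frame(theta = theta_grid, reference = Tr, focal = Tf),
    item_dif = data.frame(item = ib_r$icf_code, udif = item_udif,
                          flagged = item_udif > dif_cut),
    link = link), class = "dtf_report")
}

#' @export
print.dtf_report <- function(x, ...) {
  cat(sprintf("<dtf_report> signed DTF %.4f, unsigned DTF %.4f, %d/%d items flagged\n",
              x$sdtf, x$udtf, sum(x$item_dif$flagged), nrow(x$item_dif)))
  invisible(x)
}

#' Monte-Carlo-adjusted item difficulty
#'
#' Parametric bootstrap of the fitted model: `reps` datasets of the
#' original sample size are simulated from the estimated item bank (traits
#' standard normal), the same model type is refitted to each, and `b_mc`
#' is the per-item mean of the replicate difficulty estimates.  Failed
#' refits are dropped and counted; more than 20% failures triggers a
#' warning.
#'
#' @param fit an `irt_fit`.
#' @param reps bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @param max_cycles EM cap for the refits (default 200).
#' @return The fit's item bank with a `b_mc` column; attributes
#'   `n_failed`, `b_replicates`.
#' @export
monte_carlo_difficulty <- function(fit, reps = 500, seed = 1L,
                                   max_cycles = 200) {
  stopifnot(reps >= 2)
  seeds <- child_seeds(seed, reps)
  B <- matrix(NA_real_, nrow(fit$item_bank), reps)
  for (r in seq_len(reps)) {
    br <- tryCatch({
      sim <- generate_irt_responses(
        fit$item_bank, sim_config(n_persons = fit$n, seed = seeds[[r]]))
      refit <- suppressWarnings(
        fit_irt(sim, fit$model, n_quad = length(fit$quad$nodes),
                range = range(fit$quad$nodes), tol = 1e-4,
                max_cycles = max_cycles, start = fit$item_bank))
      refit$item_bank$b
    }, error = function(e) NULL)
    if (!is.null(br)) B[, r] <- br
  }
  failed <- colSums(is.na(B)) > 0
  if (mean(failed) > 0.2)
    warning(sprintf("%d of %d bootstrap refits failed", sum(failed), reps))
  ib <- fit$item_bank
  ib$b_mc <- rowMeans(B[, !failed, drop = FALSE])
  attr(ib, "n_failed") <- sum(failed)
  attr(ib, "b_replicates") <- B
  ib
}
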
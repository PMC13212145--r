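#' Mokken scalability coefficients
#'
#' Computes the item-pair scalability matrix Hij, the per-item Hi and the
#' total scale H for a complete dichotomous matrix.  Hij is the ratio of
#' the observed inter-item covariance to its maximum given the item
#' marginals, cov_max = min(p_i, p_j) - p_i p_j; Hi and H are the standard
#' weighted ratios (sums of covariances over sums of maximum covariances),
#' so H is a weighted mean of the Hi and each Hi of its Hij.  Perfect
#' Guttman data give Hij = Hi = H = 1.
#'
#' @param m a complete binary [response_matrix()] (>= 2 items).
#' @return An object of class `mokken_summary`: `Hij`, `Hi`, `H`,
#'   `item_popularity`.
#' @export
scalability_coefficients <- function(m) {
  X <- unclass_rm(as_response_matrix(m))
  if (anyNA(X)) stop("complete matrix required")
  J <- ncol(X)
  if (J < 2) stop("need >= 2 items")
  p <- colMeans(X)
  if (any(p %in% c(0, 1)))
    stop("zero-variance item(s): ",
         paste(colnames(X)[p %in% c(0, 1)], collapse = ", "))
  C <- crossprod(X) / nrow(X) - outer(p, p)       # covariances (population)
  Cmax <- outer(p, p, pmin) - outer(p, p)
  diag(C) <- diag(Cmax) <- NA
  Hij <- C / Cmax
  Hi <- rowSums(C, na.rm = TRUE) / rowSums(Cmax, na.rm = TRUE)
  H <- sum(C[upper.tri(C)]) / sum(Cmax[upper.tri(Cmax)])
  structure(list(Hij = Hij, Hi = Hi, H = H, item_popularity = p),
            class = "mokken_summary")
}

#' @export
print.mokken_summary <- function(x, ...) {
  cat(sprintf("<mokken_summary> %d items, total H = %.3f (Hi range %.3f-%.3f)\n",
              length(x$Hi), x$H, min(x$Hi), max(x$Hi)))
  invisible(x)
}

# Items ordered by decreasing popularity; ties broken by item id.
popularity_order <- function(X) {
  p <- colMeans(X)
  order(-p, colnames(X))
}

#' Per-person Guttman error counts
#'
#' With items ordered by decreasing popularity (sample proportion passing;
#' ties broken lexicographically by item id), a Guttman error is a pair
#' (easier, harder) where the person fails the easier item but passes the
#' harder one.  High counts flag aberrant response patterns.
#'
#' @param m a complete binary [response_matrix()].
#' @return A named integer vector of error counts per person.
#' @export
guttman_errors <- function(m) {
  X <- unclass_rm(as_response_matrix(m))
  if (anyNA(X)) stop("complete matrix required")
  X <- X[, popularity_order(X), drop = FALSE]
  # for each person: sum over positions h of x_h * (# fails among easier items)
  fails_before <- t(apply(1 - X, 1, cumsum))  # count of fails at or before pos
  J <- ncol(X)
  cnt <- rowSums(X[, -1, drop = FALSE] *
                 fails_before[, -J, drop = FALSE])
  setNames(as.integer(cnt), rownames(X))
}

#' Flag persons with extreme Guttman error counts
#'
#' Tukey's upper fence: counts above Q3 + 1.5 IQR are flagged.
#'
#' @param counts output of [guttman_errors()].
#' @return Character vector of flagged person ids.
#' @export
flag_aberrant_persons <- function(counts) {
  qs <- quantile(counts, c(0.25, 0.75))
  fence <- qs[2] + 1.5 * (qs[2] - qs[1])
  names(counts)[counts > fence]
}

#' Automated item selection for a Mokken scale
#'
#' Greedy single-scale construction in the spirit of the automated item
#' selection procedure (AISP): start from the item pair with the largest
#' Hij at or above `lower_bound`, then repeatedly add the item that
#' maximizes the scale H among candidates whose Hi with the current scale
#' is at least `lower_bound` and whose Hij with every in-scale item is
#' positive.
#'
#' @param m a complete binary [response_matrix()].
#' @param lower_bound scalability bound c (default 0.42).
#' @return A list of class `aisp_selection`: `selected` item ids, `H` of
#'   the final scale, and `excluded`.  An empty selection (no qualifying
#'   pair) is returned as such, not an error.
#' @export
aisp_select <- function(m, lower_bound = 0.42) {
  X <- unclass_rm(as_response_matrix(m))
  sc <- scalability_coefficients(X)
  J <- ncol(X)
  items <- colnames(X)
  Hij <- sc$Hij
  ut <- which(upper.tri(Hij), arr.ind = TRUE)
  vals <- Hij[ut]
  if (!length(vals) || max(vals) < lower_bound || max(vals) <= 0) {
    return(structure(list(selected = character(0), H = NA_real_,
                          excluded = items), class = "aisp_selection"))
  }
  best <- ut[which.max(vals), ]
  scale <- items[best]
  repeat {
    cand <- setdiff(items, scale)
    if (!length(cand)) break
    gains <- vapply(cand, function(it) {
      sub <- c(scale, it)
      if (any(Hij[it, scale] <= 0)) return(NA_real_)
      sc2 <- scalability_coefficients(X[, sub, drop = FALSE])
      if (sc2$Hi[it] < lower_bound) return(NA_real_)
      sc2$H
    }, 0)
    if (all(is.na(gains))) break
    scale <- c(scale, cand[which.max(gains)])
  }
  Hfinal <- scalability_coefficients(X[, scale, drop = FALSE])$H
  structure(list(selected = scale, H = Hfinal,
                 excluded = setdiff(items, scale)),
            class = "aisp_selection")
}

#' @export
print.aisp_selection <- function(x, ...) {
  if (!length(x$selected)) cat("<aisp_selection> empty selection\n")
  else cat(sprintf("<aisp_selection> %d items, scale H = %.3f\n",
                   length(x$selected), x$H))
  invisible(x)
}

#' Monotonicity check via rest-score groups
#'
#' For each item, persons are grouped by their rest score (total minus the
#' item), adjacent rest scores being merged until every group holds at
#' least `min_group_size` persons.  The item's proportion passing should be
#' non-decreasing across groups; each adjacent decrease is tested with a
#' one-sided two-proportion z test at `alpha`.
#'
#' @param m a complete binary [response_matrix()].
#' @param min_group_size minimum persons per rest-score group (default
#'   `max(10, n/10)`).
#' @param alpha significance level per adjacent comparison.
#' @return A data frame per item: `n_groups`, `n_decreases`,
#'   `n_significant`, `testable`.
#' @export
check_monotonicity <- function(m, min_group_size = NULL, alpha = 0.05) {
  X <- unclass_rm(as_response_matrix(m))
  if (anyNA(X)) stop("complete matrix required")
  n <- nrow(X)
  min_group_size <- min_group_size %||% max(10, floor(n / 10))
  res <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) == 1)
      return(data.frame(item = colnames(X)[j], n_groups = 0L,
                        n_decreases = 0L, n_significant = 0L,
                        testable = FALSE))
    rest <- rowSums(X[, -j, drop = FALSE])
    lev <- sort(unique(rest))
    sizes <- table(factor(rest, levels = lev))
    # merge adjacent rest scores left-to-right until groups are big enough
    grp <- integer(length(lev)); gid <- 1L; acc <- 0L
    for (k in seq_along(lev)) {
      grp[k] <- gid; acc <- acc + sizes[k]
      if (acc >= min_group_size && k < length(lev)) { gid <- gid + 1L; acc <- 0L }
    }
    if (acc < min_group_size && acc > 0 && gid > 1)
      grp[grp == gid] <- gid - 1L
    gmap <- grp[match(rest, lev)]
    ng <- length(unique(gmap))
    if (ng < 2)
      return(data.frame(item = colnames(X)[j], n_groups = ng,
                        n_decreases = 0L, n_significant = 0L,
                        testable = FALSE))
    props <- tapply(x, gmap, mean)
    sizes_g <- tapply(x, gmap, length)
    dec <- 0L; sig <- 0L
    for (k in seq_len(ng - 1)) {
      if (props[k + 1] < props[k]) {
        dec <- dec + 1L
        p_pool <- (props[k] * sizes_g[k] + props[k + 1] * sizes_g[k + 1]) /
          (sizes_g[k] + sizes_g[k + 1])
        se <- sqrt(p_pool * (1 - p_pool) * (1 / sizes_g[k] + 1 / sizes_g[k + 1]))
        z <- (props[k] - props[k + 1]) / max(se, 1e-12)
        if (pnorm(z, lower.tail = FALSE) < alpha) sig <- sig + 1L
      }
    }
    data.frame(item = colnames(X)[j], n_groups = ng, n_decreases = dec,
               n_significant = sig, testable = TRUE)
  })
  do.call(rbind, res)
}
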
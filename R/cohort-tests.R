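#' Cramér's V from a chi-squared statistic
#'
#' V = sqrt(chi2 / (n (min(r, c) - 1))).  For 2x2 tables the package
#' computes V from the continuity-corrected statistic, consistent with how
#' the cohort tables it reproduces were reported.
#'
#' @param chi2 chi-squared statistic.
#' @param n total count.
#' @param dims table dimensions (default 2x2).
#' @export
cramers_v <- function(chi2, n, dims = c(2, 2)) {
  sqrt(chi2 / (n * (min(dims) - 1)))
}

#' Rank epsilon-squared effect size for the Kruskal-Wallis test
#'
#' epsilon^2 = H (N + 1) / (N^2 - 1).
#'
#' @param H Kruskal-Wallis statistic.
#' @param N total sample size.
#' @export
epsilon_squared <- function(H, N) H * (N + 1) / (N^2 - 1)

#' Baseline cohort comparisons with effect sizes
#'
#' Reproduces the usual "Table 1" analysis for a grouped cohort.
#' Categorical variables are tested with Pearson's chi-squared test (Yates
#' continuity correction for 2x2 tables) and Cramér's V computed from the
#' corrected statistic; Fisher's exact test replaces the chi-squared test
#' when any expected cell count is below 5.  Continuous variables are first
#' gated by per-group Shapiro-Wilk normality tests: normal data get a Welch
#' t-test with Cohen's d, non-normal data a Kruskal-Wallis test with rank
#' epsilon-squared.
#'
#' @param data a data frame of variables to test.
#' @param group a factor (or name of a column in `data`) with >= 2 levels.
#' @param vars variables to test; defaults to every column except the group.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return A data frame of class `cohort_tests`: variable, method,
#'   statistic, df, p_value, effect_size, effect_type.
#' @export
cohort_tests <- function(data, group, vars = NULL,
                         alpha_normality = 0.05) {
  if (is.character(group) && length(group) == 1) {
    gname <- group; group <- factor(data[[group]])
  } else {
    gname <- NULL; group <- factor(group)
  }
  if (nlevels(droplevels(group)) < 2) stop("grouping needs >= 2 levels")
  if (any(table(group) == 0)) stop("empty group level")
  vars <- vars %||% setdiff(names(data), gname)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x) || is.logical(x)) {
      tab <- table(factor(x), group)
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_counts < 5)) {
        ft <- fisher.test(tab)
        chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
        data.frame(variable = v, method = "Fisher exact",
                   statistic = NA_real_, df = NA_real_, p_value = ft$p.value,
                   effect_size = cramers_v(chi2, sum(tab), dim(tab)),
                   effect_type = "Cramer V")
      } else {
        yates <- all(dim(tab) == 2)
        ct <- chisq.test(tab, correct = yates)
        data.frame(variable = v,
                   method = if (yates) "Pearson chi2 (Yates)" else "Pearson chi2",
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value,
                   effect_size = cramers_v(unname(ct$statistic), sum(tab),
                                           dim(tab)),
                   effect_type = "Cramer V")
      }
    } else {
      ok <- stats::complete.cases(x, group)
      x <- x[ok]; g <- droplevels(group[ok])
      normal <- all(vapply(split(x, g), function(xx)
        length(unique(xx)) > 2 && shapiro.test(xx)$p.value > alpha_normality,
        TRUE))
      if (normal && nlevels(g) == 2) {
        tt <- t.test(x ~ g)
        sp <- split(x, g)
        sd_pool <- sqrt(((length(sp[[1]]) - 1) * var(sp[[1]]) +
                         (length(sp[[2]]) - 1) * var(sp[[2]])) /
                        (length(x) - 2))
        data.frame(variable = v, method = "Welch t",
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   effect_size = abs(mean(sp[[1]]) - mean(sp[[2]])) / sd_pool,
                   effect_type = "Cohen d")
      } else {
        kw <- kruskal.test(x, g)
        data.frame(variable = v, method = "Kruskal-Wallis",
                   statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value,
                   effect_size = epsilon_squared(unname(kw$statistic),
                                                 length(x)),
                   effect_type = "epsilon2")
      }
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_tests", "data.frame")
  out
}

#' Winsorized correlation
#'
#' Pearson correlation after winsorizing both vectors at the `trim` and
#' `1 - trim` quantiles, with a t test on n - 2 degrees of freedom — a
#' robust convergent-validity check between the latent trait and external
#' criterion scores.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param trim winsorizing proportion per tail (default 0.2).
#' @return A list: `r`, `statistic` (t), `df`, `p_value`, `method`.
#' @export
winsorized_correlation <- function(x, y, trim = 0.2) {
  stopifnot(length(x) == length(y), length(x) >= 3, trim >= 0, trim < 0.5)
  wins <- function(v) {
    qs <- quantile(v, c(trim, 1 - trim), na.rm = TRUE)
    pmin(pmax(v, qs[1]), qs[2])
  }
  xw <- wins(x); yw <- wins(y)
  if (sd(xw) == 0 || sd(yw) == 0)
    stop("zero variance after winsorizing; correlation undefined")
  r <- cor(xw, yw)
  n <- length(x)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, statistic = tstat, df = n - 2,
       p_value = 2 * stats::pt(-abs(tstat), n - 2),
       method = "winsorized correlation")
}

#' Kendall's tau-b with tie-corrected normal test
#'
#' Wrapper around the standard tau-b estimate with the normal approximation
#' for the p value, as used to compare theoretical and
#' Monte-Carlo-adjusted item difficulties.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return A list: `tau`, `statistic` (z), `p_value`, `method`.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("tau undefined for an all-tied vector")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), statistic = unname(ct$statistic),
       p_value = ct$p.value, method = "Kendall tau-b")
}
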
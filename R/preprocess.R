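#' Dichotomize ICF qualifier data
#'
#' ICF items are rated with qualifiers 0 (no problem) through 4 (complete
#' problem).  For IRT modelling these are collapsed to a binary
#' function-coded response: qualifier 0 becomes 1 (no impairment) and
#' qualifiers 1-4 become 0 (impairment).  Missing qualifiers stay missing.
#'
#' @param raw a data frame or matrix of qualifiers in \{0,...,4, NA\};
#'   persons as rows, ICF codes as columns.
#' @return A function-coded [response_matrix()].
#' @examples
#' dichotomize_icf(matrix(c(0, 3, 1, 0), 2, dimnames = list(NULL, c("b130", "d430"))))
#' @export
dichotomize_icf <- function(raw) {
  x <- as.matrix(raw)
  bad <- which(!is.na(x) & !(x %in% 0:4), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("qualifier outside 0-4 at row %s, column %s",
                 bad[1, 1], colnames(x)[bad[1, 2]] %||% bad[1, 2]))
  response_matrix(ifelse(is.na(x), NA, as.integer(x == 0)),
                  orientation = "function",
                  person_ids = rownames(x), item_ids = colnames(x))
}

#' Flip a function-coded matrix to risk coding
#'
#' The network stage analyses risk correlations, so responses are recoded
#' entrywise: impairment = 1, no impairment = 0.  A matrix that is already
#' risk-coded is refused rather than silently double-flipped.
#'
#' @param m a function-coded [response_matrix()].
#' @return The complemented matrix with `orientation = "risk"`.
#' @export
recode_for_network <- function(m) {
  stopifnot(is_response_matrix(m))
  if (orientation(m) == "risk")
    stop("matrix is already risk-coded; refusing to flip again")
  response_matrix(1L - unclass_rm(m), "risk",
                  person_ids = rownames(m), item_ids = colnames(m))
}

#' Filter items by missingness and pseudo-constancy
#'
#' Items with a missing proportion at or above `missing_threshold` are
#' removed, as are pseudo-constant items whose minority category (among
#' non-missing responses) has proportion at or below
#' `pseudo_constant_threshold`.
#'
#' @param m a [response_matrix()].
#' @param missing_threshold removal bound on the missing proportion
#'   (default 0.30, inclusive).
#' @param pseudo_constant_threshold removal bound on the minority-category
#'   proportion (default 0.05, inclusive).
#' @return A list of class `item_filter` with the filtered `matrix` and a
#'   `report` data frame (item, reason, proportion) of removals.
#' @export
filter_items <- function(m, missing_threshold = 0.30,
                         pseudo_constant_threshold = 0.05) {
  stopifnot(missing_threshold > 0, missing_threshold < 1,
            pseudo_constant_threshold > 0, pseudo_constant_threshold < 1)
  m <- as_response_matrix(m)
  miss <- colMeans(is.na(m))
  minority <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(0)
    min(sum(col), length(col) - sum(col)) / length(col)
  })
  drop_miss <- miss >= missing_threshold
  drop_pc <- !drop_miss & minority <= pseudo_constant_threshold
  report <- rbind(
    data.frame(item = colnames(m)[drop_miss],
               reason = rep("missing", sum(drop_miss)),
               proportion = unname(miss[drop_miss])),
    data.frame(item = colnames(m)[drop_pc],
               reason = rep("pseudo-constant", sum(drop_pc)),
               proportion = unname(minority[drop_pc])))
  keep <- !(drop_miss | drop_pc)
  if (!any(keep)) stop("all items removed by filtering; empty scale")
  out <- response_matrix(unclass_rm(m)[, keep, drop = FALSE], orientation(m),
                         person_ids = rownames(m),
                         item_ids = colnames(m)[keep])
  structure(list(matrix = out, report = report), class = "item_filter")
}

#' @export
print.item_filter <- function(x, ...) {
  cat(sprintf("<item_filter> kept %d items, removed %d\n",
              ncol(x$matrix), nrow(x$report)))
  if (nrow(x$report)) print.data.frame(x$report, digits = 3)
  invisible(x)
}
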
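#' Item banks of logistic IRT parameters
#'
#' An item bank is a data frame with one row per item and the four-parameter
#' logistic (4PL) parameters: discrimination `a > 0`, difficulty `b` (logit
#' scale), lower asymptote ("guessing") `g` in \[0, 1) and upper asymptote
#' ("carelessness") `u` in (g, 1\].  Simpler models are the usual special
#' cases (3PL: u = 1; 2PL: g = 0, u = 1; 1PL: additionally a common `a`).
#' Optional columns: `b_mc` (Monte-Carlo-adjusted difficulty), `label`.
#'
#' @param icf_code character item identifiers (unique), e.g. `"d430"`.
#' @param a,b,g,u numeric parameter vectors, recycled to the item count.
#' @param b_mc optional adjusted difficulties.
#' @param label optional item descriptions.
#' @return A data frame of class `item_bank`.
#' @examples
#' item_bank(c("d430", "d475"), a = c(5.59, 1.99), b = c(1.04, 0.98))
#' @export
item_bank <- function(icf_code, a, b, g = 0, u = 1, b_mc = NULL,
                      label = NULL) {
  n <- length(icf_code)
  if (anyDuplicated(icf_code)) stop("item codes must be unique")
  ib <- data.frame(icf_code = as.character(icf_code),
                   label = if (is.null(label)) NA_character_ else label,
                   a = rep_len(a, n), b = rep_len(b, n),
                   g = rep_len(g, n), u = rep_len(u, n),
                   stringsAsFactors = FALSE)
  if (!is.null(b_mc)) ib$b_mc <- rep_len(b_mc, n)
  validate_item_bank(ib)
  class(ib) <- c("item_bank", "data.frame")
  ib
}

validate_item_bank <- function(ib) {
  with(ib, {
    if (any(!is.finite(a)) || any(a <= 0)) stop("discrimination a must be > 0")
    if (any(g < 0 | g >= 1)) stop("guessing g must lie in [0, 1)")
    if (any(u <= g | u > 1)) stop("upper asymptote u must lie in (g, 1]")
    if (any(!is.finite(b))) stop("difficulty b must be finite")
  })
  invisible(ib)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items\n", nrow(x)))
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' The packaged 43-item ICF nutrition item bank
#'
#' A published 3PLM calibration of 43 dichotomized ICF items (body functions
#' `b...` and activities/participation `d...`) measuring nutrition-associated
#' health in a 300-patient oncology cohort.  Besides the 3PL parameters it
#' carries the Monte-Carlo-adjusted difficulty `b_mc`, the normalized benefit
#' index `bi_norm` with its significance flag, the impairment profile of the
#' published worked-example patient (`impaired_example`), and whether the
#' item belongs to the 33-item maximal connected subnetwork
#' (`main_component`).
#'
#' @return An `item_bank` data frame with 43 rows.
#' @examples
#' ib <- icf_item_bank()
#' sum(ib$impaired_example)  # 23 impaired items in the worked example
#' @export
icf_item_bank <- function() {
  path <- system.file("extdata", "item_bank_3plm.tsv", package = "icfnet")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ib <- item_bank(df$icf_code, a = df$a, b = df$b, g = df$g, u = 1,
                  b_mc = df$b_mc, label = df$label)
  ib$bi_norm <- df$bi_norm
  ib$bi_significant <- df$bi_significant == 1
  ib$impaired_example <- df$impaired_example == 1
  ib$main_component <- df$main_component == 1
  ib
}

#' @rdname item_bank
#' @param file path to a tab-separated item-bank table with columns
#'   `icf_code`, `a`, `b` and optionally `label`, `g`, `u`, `b_mc`.
#' @export
read_item_bank <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  item_bank(df$icf_code, a = df$a, b = df$b, g = df$g %||% 0,
            u = df$u %||% 1, b_mc = df$b_mc, label = df$label)
}

#' @rdname item_bank
#' @param ib an `item_bank`.
#' @export
write_item_bank <- function(ib, file) {
  write.table(as.data.frame(ib), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
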
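#' Persons-by-items binary response matrix
#'
#' The basic data container of the package: a persons x items matrix with
#' entries 0, 1 or `NA`, together with a coding orientation.  In
#' *function coding* a 1 means "no impairment" (the IRT orientation, where a
#' higher total score means better functioning); in *risk coding* a 1 means
#' "impairment" (the network orientation).  The two codings are entrywise
#' complements of each other on non-missing cells.
#'
#' @param x numeric or integer matrix with entries in \{0, 1, NA\}.
#' @param orientation `"function"` (1 = unimpaired) or `"risk"`
#'   (1 = impaired).
#' @param person_ids,item_ids optional identifiers; default to the dimnames
#'   of `x` or generated `p###` / `V#` labels.  Item ids must be unique.
#' @return An object of class `response_matrix`: an integer matrix with
#'   dimnames and an `orientation` attribute.
#' @examples
#' m <- response_matrix(matrix(c(1, 0, NA, 1), 2, 2), "function")
#' orientation(m)
#' @export
response_matrix <- function(x, orientation = c("function", "risk"),
                            person_ids = NULL, item_ids = NULL) {
  orientation <- match.arg(orientation)
  x <- as.matrix(x)
  vals <- x[!is.na(x)]
  if (!all(vals %in% c(0, 1)))
    stop("response entries must be 0, 1 or NA")
  storage.mode(x) <- "integer"
  person_ids <- person_ids %||% rownames(x) %||%
    sprintf("p%03d", seq_len(nrow(x)))
  item_ids <- item_ids %||% colnames(x) %||% paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(item_ids)) stop("item ids must be unique")
  dimnames(x) <- list(person_ids, item_ids)
  attr(x, "orientation") <- orientation
  class(x) <- c("response_matrix", class(x))
  x
}

#' @rdname response_matrix
#' @param m a `response_matrix`.
#' @export
orientation <- function(m) attr(m, "orientation")

is_response_matrix <- function(x) inherits(x, "response_matrix")

as_response_matrix <- function(x, orientation = "function") {
  if (is_response_matrix(x)) x else response_matrix(x, orientation)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %s-coded, %.1f%% missing\n",
              nrow(x), ncol(x), orientation(x), 100 * mean(is.na(x))))
  invisible(x)
}

# Drop the class but keep dimnames; used before handing data to base code.
unclass_rm <- function(m) {
  attr(m, "orientation") <- NULL
  class(m) <- NULL
  m
}

#' Read and write response matrices as delimited text
#'
#' Persons are rows, ICF codes are the column headers, and an empty field is
#' a missing response.  The orientation is stored in a `# orientation:`
#' comment on the first line and recovered on read.
#'
#' @param m a [response_matrix()].
#' @param file path to a tab-separated file.
#' @return `read_responses()` returns a `response_matrix`;
#'   `write_responses()` returns `file` invisibly.
#' @export
write_responses <- function(m, file) {
  stopifnot(is_response_matrix(m))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# orientation: ", orientation(m)), con)
  df <- data.frame(person_id = rownames(m), unclass_rm(m),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_responses
#' @export
read_responses <- function(file) {
  first <- readLines(file, n = 1L)
  orient <- if (grepl("^# orientation:", first))
    trimws(sub("^# orientation:", "", first)) else "function"
  df <- read.delim(file, comment.char = "#", check.names = FALSE,
                   na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  response_matrix(m, orient)
}
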
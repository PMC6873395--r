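#' Grouped count table
#'
#' A features x samples matrix of non-negative integer counts together with
#' a sample-to-group assignment — the in-memory form of an OTU/ASV table
#' with its experimental design.
#'
#' @param counts numeric/integer matrix, features on rows, samples on
#'   columns; dimnames are used as feature and sample ids (defaults are
#'   generated when absent).
#' @param group_of named character vector mapping sample id to group label,
#'   or an unnamed vector aligned with the columns of `counts`.
#' @return an object of class `grouped_count_table`.
#' @examples
#' m <- matrix(c(0, 1, 2, 0), nrow = 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' grouped_count_table(m, c(s1 = "a", s2 = "a"))
#' @export
grouped_count_table <- function(counts, group_of) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) abort_data("count table is empty")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) abort_data("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) abort_data("duplicate sample ids")
  if (anyNA(counts)) abort_data("count table contains missing values")
  if (any(counts < 0)) abort_data("count table contains negative values")
  bad <- which(!is_wholenumber(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_data(sprintf(
      "non-integer count %s at feature '%s', sample '%s'",
      format(counts[bad[1, 1], bad[1, 2]]),
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"

  nm <- names(group_of)
  if (is.null(nm)) {
    if (length(group_of) != ncol(counts)) {
      abort_data("group_of must name every sample or align with the columns")
    }
    nm <- colnames(counts)
  }
  group_of <- stats::setNames(as.character(group_of), nm)
  missing_samples <- setdiff(colnames(counts), names(group_of))
  if (length(missing_samples) > 0L) {
    abort_data("samples without group assignment: ",
               paste(missing_samples, collapse = ", "))
  }
  group_of <- group_of[colnames(counts)]
  if (anyNA(group_of)) abort_data("missing group labels")
  structure(list(counts = counts, group_of = group_of),
            class = "grouped_count_table")
}

#' @export
print.grouped_count_table <- function(x, ...) {
  tab <- table(x$group_of)
  cat(sprintf("<grouped_count_table> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("  sparsity: %.1f%%, depth range: %s..%s\n",
              100 * mean(x$counts == 0),
              format(min(colSums(x$counts))), format(max(colSums(x$counts)))))
  invisible(x)
}

table_groups <- function(table) unique(unname(table$group_of))

group_columns <- function(table, group) {
  which(table$group_of == group)
}
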
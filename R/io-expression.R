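#' Read a normalized expression matrix
#'
#' Reads a tab-separated expression table (header row of sample identifiers,
#' first column of feature identifiers) into an `expression_matrix` object.
#' Values are expected to be normalized, log-scale intensities; the reader
#' validates finiteness only — normalization is upstream of this package.
#' Rows containing any non-numeric cell are dropped with a message giving the
#' count.
#'
#' @param path Path to a TSV file. Column 1 holds feature ids (miRNAs or
#'   genes); remaining columns are samples.
#' @param condition Single string labelling the experimental condition the
#'   profile was measured under (e.g. `"radiation"`).
#' @return An `expression_matrix`: a list with elements `condition`,
#'   `values` (numeric matrix, features x samples), `feature_ids`,
#'   `sample_ids`, and `n_dropped` (rows rejected as non-numeric).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2\ts3", "miR-1\t1\t2\t3", "miR-2\t3\t2\t1"), tf)
#' em <- read_expression(tf, condition = "demo")
#' dim(em$values)
#' @export
read_expression <- function(path, condition) {
  .check_string(path, "path")
  .check_string(condition, "condition")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 4L) {
    rlang::abort(sprintf(
      "insufficient samples in '%s': correlation needs at least 3 sample columns, found %d.",
      path, ncol(raw) - 1L
    ))
  }
  ids <- trimws(raw[[1L]])
  dup <- ids[duplicated(.norm_id(ids))]
  if (length(dup)) {
    rlang::abort(sprintf("duplicate feature id(s) in '%s': %s",
                         path, paste(unique(dup), collapse = ", ")))
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    rlang::abort(sprintf("duplicate sample id(s) in '%s'.", path))
  }
  suppressWarnings({
    vals <- vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  })
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, sample_ids))
  bad <- rowSums(!is.finite(vals)) > 0L
  if (any(bad)) {
    rlang::inform(sprintf(
      "read_expression: dropped %d row(s) with non-numeric or non-finite values.",
      sum(bad)
    ))
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0L) rlang::abort(sprintf("no numeric rows left in '%s'.", path))
  new_expression_matrix(condition, vals, n_dropped = sum(bad))
}

new_expression_matrix <- function(condition, values, n_dropped = 0L) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(
    list(
      condition = condition,
      values = values,
      feature_ids = rownames(values),
      sample_ids = colnames(values),
      n_dropped = as.integer(n_dropped)
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> condition '%s': %d features x %d samples\n",
              x$condition, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @describeIn read_expression Long-format view: one row per
#'   (feature, sample) with the measured value.
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "value") |>
    dplyr::mutate(condition = x$condition, .before = 1L)
}
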
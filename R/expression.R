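#' Expression matrix container
#'
#' An expression matrix is a plain numeric matrix (genes as rows, samples as
#' columns) carrying a declared measurement scale: `"linear"` (TPM-like,
#' non-negative), `"log10"` (log10 of linear + pseudocount), or `"scaled"`
#' (gene-wise zero-mean, unit-variance). All statistics in the package run on
#' the log10 or scaled representation; the tag exists so each stage can refuse
#' input on the wrong scale instead of silently producing nonsense.
#'
#' @param values Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids) and colnames (sample ids). All entries finite.
#' @param scale One of `"linear"`, `"log10"`, `"scaled"`.
#' @return The matrix with a `scale` attribute and class `expr_matrix`.
#' @examples
#' m <- expr_matrix(matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'                  scale = "linear")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, scale = c("linear", "log10", "scaled")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("duplicate gene ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("duplicate sample ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    abort(paste0(
      "non-finite values, first at gene ", rownames(values)[bad[1, 1]],
      ", sample ", colnames(values)[bad[1, 2]]
    ))
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param m An `expr_matrix`.
#' @export
expr_scale <- function(m) {
  attr(m, "scale") %||% "linear"
}

# rebuild the container after an elementwise transform, keeping dimnames
set_expr_scale <- function(m, scale) {
  attr(m, "scale") <- scale
  class(m) <- c("expr_matrix", "matrix", "array")
  m
}

assert_expr_scale <- function(m, expected, what) {
  sc <- expr_scale(m)
  if (!sc %in% expected) {
    abort(paste0(
      what, " expects an expression matrix on scale ",
      paste(expected, collapse = " or "), ", got '", sc, "'."
    ))
  }
  invisible(m)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x), " genes x ", ncol(x), " samples, scale = '",
    expr_scale(x), "'\n",
    sep = ""
  )
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 4))
  invisible(x)
}

#' @describeIn expr_matrix Long-format tibble (gene_id, sample_id, value).
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Export a log10 matrix as TPM-like linear values
#'
#' Inverse of [log_transform()]: `10^x - pseudocount`, clamped at zero so
#' round-tripping synthetic log10 data yields a valid linear matrix.
#'
#' @param m An `expr_matrix` on the log10 scale.
#' @param pseudocount Pseudocount used in the forward transform.
#' @return An `expr_matrix` on the linear scale.
#' @export
to_linear <- function(m, pseudocount = 1) {
  assert_expr_scale(m, "log10", "to_linear()")
  out <- pmax(10^unclass(m) - pseudocount, 0)
  expr_matrix(out, scale = "linear")
}

check_samples_aligned <- function(m, samples) {
  if (!all(c("sample_id", "environment") %in% names(samples))) {
    abort("sample table must have at least sample_id and environment columns.")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample table has duplicated sample_id entries.")
  }
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing)) {
    abort(paste0(
      "matrix columns absent from sample table: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# reorder/subset the sample table to the matrix columns
samples_for <- function(m, samples) {
  check_samples_aligned(m, samples)
  samples[match(colnames(m), samples$sample_id), , drop = FALSE]
}
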
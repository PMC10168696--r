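#' Read an expression matrix
#'
#' Dense TSV/CSV (genes as rows, first column gene ids, header = sample
#' ids) or MatrixMarket triplets with companion gene- and sample-id files.
#' Leading `#` comment lines are skipped. The matrix is validated (unique
#' ids, finite values) before use; parse problems name the offending gene
#' and sample.
#'
#' @param path File path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param scale Declared measurement scale of the stored values.
#' @param gene_file,sample_file Companion id files (one id per line),
#'   required for `format = "mtx"`.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            scale = "linear",
                            gene_file = NULL, sample_file = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(gene_file) || is.null(sample_file)) {
      abort("MTX input needs `gene_file` and `sample_file`.")
    }
    mm <- tryCatch(Matrix::readMM(path), error = function(e) {
      abort(paste0("MTX parse error in ", path, ": ", conditionMessage(e)))
    })
    genes <- readr::read_lines(gene_file)
    smps <- readr::read_lines(sample_file)
    if (nrow(mm) != length(genes) || ncol(mm) != length(smps)) {
      abort("MTX dimensions do not match the id files.")
    }
    v <- as.matrix(mm)
    dimnames(v) <- list(genes, smps)
    return(expr_matrix(v, scale = scale))
  }

  delim <- if (format == "tsv") "\t" else ","
  # cells come in as text and go through R's correctly-rounded strtod so
  # written doubles round-trip bit-exactly
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            .default = readr::col_character()
                          ))
  if (nrow(readr::problems(df)) > 0) {
    pr <- readr::problems(df)[1, ]
    abort(paste0("parse error at line ", pr$row, ": ", pr$expected))
  }
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("duplicate gene ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  v <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                               dimnames = list(gene_ids, colnames(raw))))
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    abort(paste0("NA or non-numeric cell at gene ", gene_ids[bad[1]],
                 ", sample ", colnames(v)[bad[2]]))
  }
  expr_matrix(v, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Genes as rows; a `# driftrescue` comment header records the scale and an
#' optional seed so every artifact declares its provenance. Round-trips
#' through [read_expression()].
#'
#' @param m An [expr_matrix()].
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @export
write_expression <- function(m, path, seed = NULL) {
  header <- paste0(
    "# driftrescue v", as.character(utils::packageVersion("driftrescue")),
    " scale=", expr_scale(m),
    if (!is.null(seed)) paste0(" seed=", seed)
  )
  vals <- unclass(m)
  # %.17g guarantees doubles survive the text round trip bit-exactly
  txt <- apply(vals, 2, function(col) sprintf("%.17g", col))
  df <- dplyr::bind_cols(tibble(gene_id = rownames(m)),
                         as_tibble(txt))
  readr::write_lines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write a sample table
#'
#' TSV with columns sample_id, donor, environment, timepoint_h, batch and
#' optionally layer; `#` comment lines are skipped.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if ("timepoint_h" %in% names(df)) {
    df$timepoint_h <- as.numeric(df$timepoint_h) # all-NA columns guess logical
  }
  need <- c("sample_id", "environment")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("sample table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id entries.")
  df
}

#' @rdname read_sample_table
#' @param samples Sample tibble.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' Pseudobulk aggregation
#'
#' Collapses single-cell-shaped columns to replicate-level means, producing
#' a bulk-like matrix for the rescue contrasts.
#'
#' @param m An [expr_matrix()] whose columns are cells.
#' @param groups Named character vector mapping every column (cell) of `m`
#'   to a replicate id.
#' @return An [expr_matrix()] with one column per replicate.
#' @export
pseudobulk <- function(m, groups) {
  if (is.null(names(groups))) {
    if (length(groups) != ncol(m)) {
      abort("`groups` must map every cell to a replicate.")
    }
    names(groups) <- colnames(m)
  }
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing)) {
    abort(paste0("cells without a replicate: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  groups <- groups[colnames(m)]
  reps <- unique(groups)
  v <- vapply(reps, function(r) {
    idx <- which(groups == r)
    if (length(idx) == 0) abort(paste0("empty replicate: ", r))
    rowMeans(unclass(m)[, idx, drop = FALSE])
  }, numeric(nrow(m)))
  if (!is.matrix(v)) v <- matrix(v, nrow = nrow(m))
  dimnames(v) <- list(rownames(m), reps)
  expr_matrix(v, scale = expr_scale(m))
}
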
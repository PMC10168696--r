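#' Sample-space principal component analysis
#'
#' PCA with samples as observations, run on gene-scaled data (the scale tag
#' is enforced so variance ratios are comparable across runs). Components are
#' computed by singular value decomposition of the column-centered
#' sample x gene matrix, with a deterministic sign convention: within each
#' component the largest-magnitude gene loading is positive.
#'
#' @param m An [expr_matrix()] with scale `"scaled"` (see [scale_genes()]).
#' @param n_components Number of components to retain (default
#'   `min(n_samples, n_genes)`).
#' @return An `expr_pca` object: `scores` (sample x component),
#'   `variance_ratio` (per-component fraction of total variance, all
#'   components), `loadings` (gene x component), `sdev`.
#' @examples
#' set.seed(1)
#' v <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' p <- pca_expression(scale_genes(expr_matrix(v, "log10")))
#' glance(p)
#' @export
pca_expression <- function(m, n_components = NULL) {
  assert_expr_scale(m, "scaled", "pca_expression()")
  x <- t(unclass(m)) # samples x genes
  k_max <- min(dim(x))
  n_components <- n_components %||% k_max
  if (n_components > k_max || n_components < 1) {
    abort(paste0("`n_components` must be in 1..", k_max))
  }
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  # sign convention: largest-magnitude loading positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  sv$u <- sweep(sv$u, 2, flip, `*`)
  sv$v <- sweep(sv$v, 2, flip, `*`)

  d2 <- sv$d^2
  variance_ratio <- d2 / sum(d2)
  keep <- seq_len(n_components)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  dimnames(scores) <- list(rownames(x), paste0("PC", keep))
  loadings <- sv$v[, keep, drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("PC", keep))

  structure(
    list(
      scores = scores,
      variance_ratio = variance_ratio,
      loadings = loadings,
      sdev = sv$d / sqrt(max(1, nrow(x) - 1))
    ),
    class = "expr_pca"
  )
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("<expr_pca> ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components retained\n", sep = "")
  vr <- round(100 * x$variance_ratio[seq_len(min(5, length(x$variance_ratio)))], 1)
  cat("variance explained (%): ", paste(vr, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn pca_expression Per-sample scores as a tibble (one row per
#'   sample x component).
#' @param x An `expr_pca`.
#' @param ... Unused.
#' @export
tidy.expr_pca <- function(x, ...) {
  scores <- x$scores
  tibble(
    sample_id = rep(rownames(scores), times = ncol(scores)),
    component = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  )
}

#' @describeIn pca_expression One row per component with its variance ratio.
#' @export
glance.expr_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$variance_ratio)),
    variance_ratio = x$variance_ratio
  )
}

#' @describeIn pca_expression Score plot of two components, optionally
#'   colored by a sample-table column.
#' @param object An `expr_pca`.
#' @param samples Optional sample table with `sample_id` and `color_by`.
#' @param components Two components to plot.
#' @param color_by Column of `samples` used for the point color.
#' @export
autoplot.expr_pca <- function(object, samples = NULL,
                              components = c("PC1", "PC2"),
                              color_by = "environment", ...) {
  df <- as_tibble(object$scores[, components, drop = FALSE])
  names(df) <- c("x", "y")
  df$sample_id <- rownames(object$scores)
  if (!is.null(samples)) {
    df[[color_by]] <- samples[[color_by]][match(df$sample_id, samples$sample_id)]
  }
  pct <- round(100 * object$variance_ratio[match(
    components, paste0("PC", seq_along(object$variance_ratio))
  )], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = paste0(components[1], " (", pct[1], "%)"),
      y = paste0(components[2], " (", pct[2], "%)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data[[color_by]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
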
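#' Biweight midcorrelation
#'
#' Robust correlation built on Tukey biweights around the median. For a
#' vector x: `u_i = (x_i - median(x)) / (9 * MAD(x))` with the unscaled
#' median absolute deviation, weights `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]`,
#' and the correlation is the inner product of the weight-normalized
#' deviations of x and y. When `MAD(x) = 0` the biweight is undefined and
#' that vector falls back to its Pearson standardization (mean-centered,
#' unit weights). A vector that is entirely constant yields `NA` (undefined
#' correlation).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param max_p_outliers Cap on the proportion of observations per side that
#'   may receive zero weight (default 1 = the plain formula). Values below 1
#'   rescale `u` so that at most this fraction of points on each side falls
#'   beyond `|u| >= 1`; use ~0.05 when correlating strongly bimodal
#'   variables such as condition-driven module eigengenes, where the plain
#'   biweight would discard one whole condition as outliers.
#' @return `bicor()`: the correlation in `[-1, 1]` (or `NA`).
#'   `bicor_with_p()`: a list with `r`, `p` (two-sided Student-t
#'   approximation, `t = r * sqrt((n - 2) / (1 - r^2))`) and `n`.
#' @examples
#' x <- c(1, 2, 3, 4, 10)
#' bicor(x, x)
#' bicor_with_p(x, rev(x))
#' @export
bicor <- function(x, y, max_p_outliers = 1) {
  check_bicor_input(x, y)
  a <- bicor_prepare_vec(x, max_p_outliers)
  b <- bicor_prepare_vec(y, max_p_outliers)
  if (is.null(a) || is.null(b)) return(NA_real_)
  r <- sum(a * b)
  max(-1, min(1, r))
}

#' @rdname bicor
#' @export
bicor_with_p <- function(x, y, max_p_outliers = 1) {
  check_bicor_input(x, y)
  r <- bicor(x, y, max_p_outliers)
  n <- length(x)
  list(r = r, p = cor_t_pvalue(r, n), n = n)
}

#' Pairwise biweight midcorrelation of matrix rows
#'
#' @param x Numeric matrix; correlations are computed between rows.
#' @param y Optional second matrix with the same number of columns; if
#'   given, the result is the `nrow(x) x nrow(y)` cross-correlation matrix.
#' @return Matrix of biweight midcorrelations (`NA` rows for constant genes).
#' @export
bicor_matrix <- function(x, y = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) < 3) abort("bicor needs n >= 3 observations.")
  a <- bicor_prepare_rows(x)
  if (is.null(y)) {
    r <- tcrossprod(a)
  } else {
    if (!is.matrix(y)) y <- matrix(y, nrow = 1)
    if (ncol(y) != ncol(x)) abort("x and y must have the same column count.")
    r <- tcrossprod(a, bicor_prepare_rows(y))
  }
  pmin(pmax(r, -1), 1)
}

check_bicor_input <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("bicor needs n >= 3 observations.")
  invisible(TRUE)
}

# weight-normalized deviations of one vector; NULL if constant
bicor_prepare_vec <- function(x, max_p_outliers = 1) {
  med <- median(x)
  mad_u <- median(abs(x - med))
  if (mad_u == 0) {
    a <- x - mean(x) # Pearson fallback
  } else {
    u <- (x - med) / (9 * mad_u)
    u <- cap_outlier_u(u, max_p_outliers)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a <- (x - med) * w
  }
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) return(NULL)
  a / nrm
}

# rowwise version; constant rows become all-NA
bicor_prepare_rows <- function(x) {
  med <- apply(x, 1, median)
  dev <- x - med
  mad_u <- apply(abs(dev), 1, median)
  a <- matrix(0, nrow(x), ncol(x))
  ok <- mad_u > 0
  if (any(ok)) {
    u <- dev[ok, , drop = FALSE] / (9 * mad_u[ok])
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a[ok, ] <- dev[ok, , drop = FALSE] * w
  }
  if (any(!ok)) {
    a[!ok, ] <- x[!ok, , drop = FALSE] - rowMeans(x[!ok, , drop = FALSE])
  }
  nrm <- sqrt(rowSums(a^2))
  bad <- nrm == 0
  nrm[bad] <- 1
  a <- a / nrm
  a[bad, ] <- NA_real_
  rownames(a) <- rownames(x)
  a
}

# rescale u so at most max_p_outliers of points per side sit beyond |u| = 1
cap_outlier_u <- function(u, max_p_outliers) {
  if (max_p_outliers >= 1) return(u)
  q_l <- quantile(u, max_p_outliers, names = FALSE)
  q_u <- quantile(u, 1 - max_p_outliers, names = FALSE)
  if (q_l < -1) u[u < 0] <- u[u < 0] / (-q_l)
  if (q_u > 1) u[u > 0] <- u[u > 0] / q_u
  u
}

# two-sided p from the Student-t approximation for a correlation
cor_t_pvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t_stat), df = n - 2)
}
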
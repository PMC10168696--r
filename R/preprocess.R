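#' Log10 transform of a linear-scale expression matrix
#'
#' `log10(value + pseudocount)`, the working scale of every downstream
#' statistic in the package.
#'
#' @param m An [expr_matrix()] on the linear scale, all values >= 0.
#' @param pseudocount Positive offset added before taking logs (default 1, so
#'   zeros map to zero).
#' @return An [expr_matrix()] with scale `"log10"`.
#' @examples
#' m <- expr_matrix(matrix(c(0, 99, 9, 1), 2, 2,
#'                         dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'                  "linear")
#' log_transform(m)
#' @export
log_transform <- function(m, pseudocount = 1) {
  assert_expr_scale(m, "linear", "log_transform()")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number.")
  }
  if (any(m < 0)) {
    bad <- unique(rownames(m)[which(unclass(m) < 0, arr.ind = TRUE)[, 1]])
    abort(paste0(
      "negative values on the linear scale for genes: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  expr_matrix(log10(unclass(m) + pseudocount), scale = "log10")
}

#' Gene-wise scaling to zero mean and unit variance
#'
#' Centers and scales every gene row (sample sd, n - 1 denominator).
#' Constant genes are centered only and flagged in the `constant_genes`
#' attribute rather than divided by zero.
#'
#' @param m An [expr_matrix()] with at least 2 samples.
#' @return An [expr_matrix()] with scale `"scaled"`; attribute
#'   `constant_genes` lists zero-variance gene ids (possibly empty).
#' @examples
#' m <- expr_matrix(matrix(c(1, 5, 2, 5, 3, 5), 2, 3,
#'                         dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'                  "log10")
#' scale_genes(m)
#' @export
scale_genes <- function(m) {
  if (ncol(m) < 2) abort("scale_genes() needs at least 2 samples.")
  v <- unclass(m)
  mu <- rowMeans(v)
  v <- v - mu
  s <- sqrt(rowSums(v^2) / (ncol(v) - 1))
  constant <- s == 0
  s[constant] <- 1
  out <- expr_matrix(v / s, scale = "scaled")
  attr(out, "constant_genes") <- rownames(m)[constant]
  out
}

#' Empirical-Bayes batch adjustment
#'
#' Removes additive and multiplicative per-gene batch effects with the
#' standardize / shrink / back-transform scheme: each gene is standardized to
#' its grand mean and pooled variance, per-batch location (gamma) and scale
#' (delta^2) effects are estimated, shrunk toward their across-gene prior by
#' empirical Bayes, and the data are back-transformed. No covariates are
#' modelled (intercept-only design).
#'
#' `mode = "parametric"` uses the normal / inverse-gamma conjugate priors
#' with the usual iterative posterior-mean solution. `mode = "nonparametric"`
#' integrates the posterior by Monte Carlo: `n_draws` (gamma, delta^2) pairs
#' are drawn from the empirical distribution of the per-gene estimates
#' (excluding the gene itself) and averaged with likelihood weights, computed
#' in log space for stability.
#'
#' @param m An [expr_matrix()] (any scale; the tag is preserved).
#' @param batches Batch label per sample (character/factor, length
#'   `ncol(m)`), or the name is taken from a sample table's `batch` column.
#'   At least 2 batches, each with >= 2 samples; a single unique label
#'   returns the input unchanged.
#' @param mode `"parametric"` (default) or `"nonparametric"`.
#' @param n_draws Monte-Carlo draws for the nonparametric mode.
#' @param seed Seed for the Monte-Carlo draws (nonparametric mode only).
#' @param conv Convergence tolerance of the parametric iteration.
#' @param var_floor Variance floor guarding zero-variance genes inside
#'   standardization.
#' @return An adjusted [expr_matrix()] on the same scale tag.
#' @examples
#' set.seed(1)
#' v <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' v[, 6:10] <- v[, 6:10] + 1  # batch shift
#' m <- expr_matrix(v, "log10")
#' adj <- eb_batch_adjust(m, rep(c("A", "B"), each = 5))
#' @export
eb_batch_adjust <- function(m, batches,
                            mode = c("parametric", "nonparametric"),
                            n_draws = 10000, seed = 1,
                            conv = 1e-4, var_floor = 1e-8) {
  mode <- match.arg(mode)
  if (length(batches) != ncol(m)) {
    abort("`batches` must have one label per sample.")
  }
  batches <- as.character(batches)
  if (is.factor(batches)) batches <- droplevels(batches)
  tab <- table(batches)
  if (any(tab < 2)) {
    abort(paste0(
      "every batch needs >= 2 samples; offending: ",
      paste(names(tab)[tab < 2], collapse = ", ")
    ))
  }
  levels <- names(tab)
  if (length(levels) == 1) {
    return(m) # nothing to adjust
  }

  v <- unclass(m)
  n <- ncol(v)
  batch_idx <- lapply(levels, function(b) which(batches == b))
  n_b <- lengths(batch_idx)

  # standardize: grand mean weighted by batch size, pooled residual variance
  batch_means <- vapply(batch_idx, function(i) rowMeans(v[, i, drop = FALSE]),
                        numeric(nrow(v)))
  grand <- as.vector(batch_means %*% (n_b / n))
  resid <- v
  for (j in seq_along(levels)) {
    resid[, batch_idx[[j]]] <- v[, batch_idx[[j]]] - batch_means[, j]
  }
  pooled_var <- pmax(rowSums(resid^2) / n, var_floor)
  z <- (v - grand) / sqrt(pooled_var)

  gamma_star <- delta_star <- matrix(0, nrow(v), length(levels))
  for (j in seq_along(levels)) {
    zb <- z[, batch_idx[[j]], drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- pmax(apply(zb, 1, var), var_floor)
    if (mode == "parametric") {
      post <- eb_parametric(zb, g_hat, d_hat, conv)
    } else {
      post <- eb_nonparametric(zb, g_hat, d_hat, n_draws,
                               seed = gen_seed(seed, 7L + j))
    }
    gamma_star[, j] <- post$gamma
    delta_star[, j] <- pmax(post$delta, var_floor)
  }

  out <- z
  for (j in seq_along(levels)) {
    out[, batch_idx[[j]]] <-
      (z[, batch_idx[[j]]] - gamma_star[, j]) / sqrt(delta_star[, j])
  }
  out <- out * sqrt(pooled_var) + grand
  dimnames(out) <- dimnames(v)
  expr_matrix(out, scale = expr_scale(m))
}

# parametric conjugate shrinkage, iterated to convergence
eb_parametric <- function(zb, g_hat, d_hat, conv) {
  n_b <- ncol(zb)
  g_bar <- mean(g_hat)
  t2 <- var(g_hat)
  m_d <- mean(d_hat)
  s2_d <- var(d_hat)
  if (!is.finite(s2_d) || s2_d == 0) s2_d <- 1e-8
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  g_new <- g_hat
  d_new <- d_hat
  change <- 1
  while (change > conv) {
    g_old <- g_new
    d_old <- d_new
    g_new <- (n_b * t2 * g_hat + d_old * g_bar) / (n_b * t2 + d_old)
    sum2 <- rowSums((zb - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n_b / 2 + a_prior - 1)
    change <- max(
      abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
      abs(d_new - d_old) / pmax(abs(d_old), 1e-12)
    )
  }
  list(gamma = g_new, delta = d_new)
}

# Monte-Carlo posterior integration with likelihood weights (log space)
eb_nonparametric <- function(zb, g_hat, d_hat, n_draws, seed) {
  g <- nrow(zb)
  n_b <- ncol(zb)
  s_sum <- rowSums(zb)
  s_sq <- rowSums(zb^2)

  set.seed(seed)
  if (g - 1 <= n_draws) {
    draw_of <- function(gene) setdiff(seq_len(g), gene)
  } else {
    pool <- sample.int(g, n_draws)
    draw_of <- function(gene) pool[pool != gene]
  }

  gamma_out <- delta_out <- numeric(g)
  for (gene in seq_len(g)) {
    d <- draw_of(gene)
    gd <- g_hat[d]
    dd <- d_hat[d]
    ss <- s_sq[gene] - 2 * gd * s_sum[gene] + n_b * gd^2
    log_lik <- -0.5 * n_b * log(2 * pi * dd) - ss / (2 * dd)
    w <- exp(log_lik - max(log_lik))
    w <- w / sum(w)
    gamma_out[gene] <- sum(w * gd)
    delta_out[gene] <- sum(w * dd)
  }
  list(gamma = gamma_out, delta = delta_out)
}
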
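#' Welch's t-test
#'
#' Two-sample t-test with unequal variances: `t = (mean(a) - mean(b)) /
#' sqrt(s2_a/n_a + s2_b/n_b)`, Welch-Satterthwaite degrees of freedom, and a
#' two-sided p-value from the t distribution. If both groups are constant
#' and equal the statistic is 0 with p = 1; constant and unequal yields the
#' infinite-t sentinel with p = 0.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return List with `t`, `df`, `p`, `delta` (`mean(a) - mean(b)`).
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("welch_t() needs >= 2 values per group.")
  }
  w <- row_welch(rbind(c(a, b)), seq_along(a), length(a) + seq_along(b))
  list(t = w$t_stat, df = w$df, p = w$p, delta = w$delta)
}

# vectorized Welch over matrix rows; idx1/idx2 are column indices
row_welch <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- length(idx1)
  n2 <- length(idx2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  delta <- m1 - m2
  t_stat <- ifelse(se2 > 0, delta / sqrt(se2),
                   ifelse(delta == 0, 0, Inf * sign(delta)))
  df <- ifelse(
    se2 > 0,
    se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
    n1 + n2 - 2
  )
  p <- ifelse(is.finite(t_stat), 2 * pt(-abs(t_stat), df), 0)
  p[t_stat == 0 & se2 == 0] <- 1
  tibble(delta = delta, t_stat = t_stat, df = df, p = p,
         mean1 = m1, mean2 = m2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`; with alpha 0.05 over 20,000 transcriptome-wide tests
#'   this is the per-gene threshold 2.5e-6.
#' @examples
#' bonferroni_threshold(0.05, 20000)
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  if (!is.numeric(m) || m < 1) abort("`m` must be a positive test count.")
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1, input order preserved);
#' delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1] with no missing entries.")
  }
  p.adjust(p, method = "BH")
}

#' Per-gene drift screen between two environments
#'
#' For each gene, runs Welch's t-test between the contrast groups and the
#' biweight midcorrelation against the condition indicator, applies BH-FDR
#' across expressed genes, and flags drifted genes by the configured rule
#' (Bonferroni `p < alpha / m` by default, or `q < alpha` with
#' `rule = "fdr"`). Group 1 is the in-vivo (cord) side, so `delta > 0` and
#' `direction = "up"` mean higher in cord.
#'
#' "Expressed" defaults to genes whose mean linear-scale expression (10^x on
#' the log10 working scale) reaches `expressed_min` in at least one contrast
#' group; pass `expressed` explicitly for matrices on other scales.
#'
#' @param m An [expr_matrix()] (log10 scale recommended: deltas are then in
#'   log10 units).
#' @param samples Sample table with `sample_id` and `environment`.
#' @param group1 Environment label(s) of the reference (cord) group.
#' @param group2 Environment label(s) of the comparison (culture) group.
#' @param rule `"bonferroni"` or `"fdr"`.
#' @param alpha Significance level of the rule.
#' @param m_tests Bonferroni denominator; defaults to the number of
#'   expressed genes. Set `m_tests = 20000` to reproduce the fixed
#'   transcriptome-wide threshold 2.5e-6.
#' @param expressed Optional logical vector (one per gene) overriding the
#'   expressed rule.
#' @param expressed_min Linear-scale expression floor for the default rule.
#' @return A `drift_table` tibble: gene_id, delta, t_stat, df, p, q,
#'   bicor_r, bicor_p, direction, expressed, drifted; summary counts as
#'   attributes (see [glance.drift_table()]).
#' @export
drift_screen <- function(m, samples,
                         group1 = "cord",
                         group2 = c("early_culture", "late_culture"),
                         rule = c("bonferroni", "fdr"),
                         alpha = 0.05,
                         m_tests = NULL,
                         expressed = NULL,
                         expressed_min = 1) {
  rule <- match.arg(rule)
  smp <- samples_for(m, samples)
  idx1 <- which(smp$environment %in% group1)
  idx2 <- which(smp$environment %in% group2)
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort("both contrast groups must be present with >= 2 samples.")
  }
  x <- unclass(m)
  w <- row_welch(x, idx1, idx2)

  ind <- numeric(ncol(x))
  ind[idx1] <- 1
  keep <- c(idx1, idx2)
  br <- as.vector(bicor_matrix(x[, keep, drop = FALSE],
                               matrix(ind[keep], nrow = 1)))
  n_bi <- length(keep)
  bp <- vapply(br, cor_t_pvalue, numeric(1), n = n_bi)

  if (is.null(expressed)) {
    if (expr_scale(m) == "log10") {
      lin <- 10^x
      expressed <- rowMeans(lin[, idx1, drop = FALSE]) >= expressed_min |
        rowMeans(lin[, idx2, drop = FALSE]) >= expressed_min
    } else {
      expressed <- rep(TRUE, nrow(x))
    }
  }
  if (length(expressed) != nrow(x)) {
    abort("`expressed` must have one flag per gene.")
  }

  n_expressed <- sum(expressed)
  if (n_expressed == 0) abort("no expressed genes to test.")
  m_tests <- m_tests %||% n_expressed

  q <- rep(NA_real_, nrow(x))
  q[expressed] <- bh_fdr(w$p[expressed])
  drifted <- expressed & if (rule == "bonferroni") {
    w$p < bonferroni_threshold(alpha, m_tests)
  } else {
    !is.na(q) & q < alpha
  }
  direction <- dplyr::case_when(
    !drifted ~ "ns",
    w$delta > 0 ~ "up",
    w$delta < 0 ~ "down",
    TRUE ~ "ns"
  )

  out <- tibble(
    gene_id = rownames(x),
    delta = w$delta, t_stat = w$t_stat, df = w$df, p = w$p, q = q,
    bicor_r = br, bicor_p = bp,
    direction = direction, expressed = expressed, drifted = drifted
  )
  class(out) <- c("drift_table", class(out))
  attr(out, "summary") <- list(
    n_genes = nrow(out),
    n_expressed = n_expressed,
    n_drifted = sum(drifted),
    fraction_drifted = sum(drifted) / n_expressed,
    rule = rule, alpha = alpha, m_tests = m_tests,
    group1 = group1, group2 = group2
  )
  out
}

#' @describeIn drift_screen One-row tibble with the screen summary
#'   (n_expressed, n_drifted, fraction_drifted, rule).
#' @param x A `drift_table`.
#' @param ... Unused.
#' @export
glance.drift_table <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(
    n_genes = s$n_genes, n_expressed = s$n_expressed,
    n_drifted = s$n_drifted, fraction_drifted = s$fraction_drifted,
    rule = s$rule, alpha = s$alpha, m_tests = s$m_tests
  )
}

#' Differential contrast for a perturbation
#'
#' Welch screen for a perturbation-vs-control contrast (flow vs static,
#' co-culture vs mono-culture), with BH-FDR over all tested genes. Positive
#' `t_stat` means higher under the perturbation.
#'
#' @inheritParams drift_screen
#' @param group1 Environment label(s) of the perturbed group.
#' @param group2 Environment label(s) of the control group.
#' @return Tibble: gene_id, delta, t_stat, df, p, q.
#' @export
de_contrast <- function(m, samples, group1, group2) {
  smp <- samples_for(m, samples)
  idx1 <- which(smp$environment %in% group1)
  idx2 <- which(smp$environment %in% group2)
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort("both contrast groups must be present with >= 2 samples.")
  }
  w <- row_welch(unclass(m), idx1, idx2)
  tibble(
    gene_id = rownames(m),
    delta = w$delta, t_stat = w$t_stat, df = w$df, p = w$p,
    q = bh_fdr(w$p)
  )
}

#' Two-set overlap within a universe
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all considered genes.
#' @return Tibble with the four disjoint counts `a_only`, `b_only`, `both`,
#'   `neither`, summing to `length(universe)`.
#' @examples
#' overlap_report(c("g1", "g2"), c("g2", "g3"), paste0("g", 1:5))
#' @export
overlap_report <- function(set_a, set_b, universe) {
  if (anyDuplicated(universe)) abort("`universe` must not contain duplicates.")
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    abort(paste0(
      "elements outside the universe: ",
      paste(head(c(out_a, out_b), 5), collapse = ", ")
    ))
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tibble(
    a_only = sum(in_a & !in_b),
    b_only = sum(!in_a & in_b),
    both = sum(in_a & in_b),
    neither = sum(!in_a & !in_b)
  )
}
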
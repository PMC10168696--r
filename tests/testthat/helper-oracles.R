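# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's own code paths.

oracle_bicor <- function(x, y) {
  prep <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) {
      a <- v - mean(v)
    } else {
      u <- (v - med) / (9 * madv)
      w <- numeric(length(v))
      for (i in seq_along(v)) {
        w[i] <- if (abs(u[i]) < 1) (1 - u[i]^2)^2 else 0
      }
      a <- (v - med) * w
    }
    a / sqrt(sum(a^2))
  }
  sum(prep(x) * prep(y))
}

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, ])
  omega <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        omega[i, j] <- 1
      } else {
        l_ij <- 0
        for (u in seq_len(n)) l_ij <- l_ij + a[i, u] * a[u, j]
        omega[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      }
    }
  }
  omega
}

oracle_ols <- function(y, t) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(origin = beta[1], slope = beta[2])
}

oracle_group_means <- function(x, groups) {
  out <- matrix(NA_real_, nrow(x), length(unique(groups)))
  for (j in seq_along(unique(groups))) {
    g <- unique(groups)[j]
    for (i in seq_len(nrow(x))) {
      out[i, j] <- mean(x[i, groups == g])
    }
  }
  colnames(out) <- unique(groups)
  out
}

oracle_similar <- function(avg, ref, s) {
  hits <- character(0)
  for (i in seq_len(nrow(avg))) {
    if (all(abs(avg[i, ] - ref) <= s)) hits <- c(hits, rownames(avg)[i])
  }
  hits
}

oracle_divergent <- function(avg, ref, s) {
  hits <- character(0)
  for (i in seq_len(nrow(avg))) {
    if (all(abs(avg[i, ] - ref) > s)) hits <- c(hits, rownames(avg)[i])
  }
  hits
}

oracle_welch <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# mean silhouette of a binary labelling on a 1-d score
sil_1d <- function(score, lab) {
  s <- vapply(seq_along(score), function(i) {
    own <- abs(score[i] - score[lab == lab[i]])
    a <- sum(own) / (length(own) - 1)
    b <- mean(abs(score[i] - score[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

rand_expr <- function(n_g, n_s, seed = 1, scale = "log10") {
  set.seed(seed)
  v <- matrix(rnorm(n_g * n_s), n_g, n_s,
              dimnames = list(sprintf("g%04d", seq_len(n_g)),
                              sprintf("s%03d", seq_len(n_s))))
  expr_matrix(v, scale)
}

# minimal drift_table for classification tests
fake_drift_table <- function(gene_id, t_stat, q, drifted,
                             n_expressed = length(gene_id)) {
  out <- tibble::tibble(
    gene_id = gene_id, delta = t_stat, t_stat = t_stat,
    df = 10, p = q, q = q,
    bicor_r = 0, bicor_p = 1,
    direction = ifelse(!drifted, "ns", ifelse(t_stat > 0, "up", "down")),
    expressed = TRUE, drifted = drifted
  )
  class(out) <- c("drift_table", class(out))
  attr(out, "summary") <- list(
    n_genes = nrow(out), n_expressed = n_expressed,
    n_drifted = sum(drifted), fraction_drifted = sum(drifted) / n_expressed,
    rule = "fdr", alpha = 0.05, m_tests = n_expressed,
    group1 = "cord", group2 = "culture"
  )
  out
}

fake_de <- function(gene_id, t_stat, q) {
  tibble::tibble(gene_id = gene_id, delta = t_stat, t_stat = t_stat,
                 df = 10, p = q, q = q)
}
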
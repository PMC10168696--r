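test_that("signed-hybrid adjacency clips negatives and matches brute force", {
  set.seed(1)
  f <- rnorm(12)
  v <- rbind(a = f + rnorm(12, 0, 1e-8), b = -f + rnorm(12, 0, 1e-8),
             c = rnorm(12))
  colnames(v) <- paste0("s", 1:12)
  m <- scale_genes(expr_matrix(v, "log10"))
  a <- adjacency_signed_hybrid(m)
  expect_equal(a["a", "b"], 0) # anti-correlated pair is clipped
  expect_equal(diag(a), rep(0, 3), ignore_attr = TRUE)

  m2 <- scale_genes(rand_expr(20, 10, seed = 2))
  a2 <- adjacency_signed_hybrid(m2, network_params(beta = 3))
  x <- unclass(m2)
  for (i in 1:20) {
    for (j in 1:20) {
      want <- if (i == j) 0 else max(oracle_bicor(x[i, ], x[j, ]), 0)^3
      expect_equal(a2[i, j], want, tolerance = 1e-12)
    }
  }
  expect_error(adjacency_signed_hybrid(scale_genes(rand_expr(5, 3))),
               "4 samples")
})

test_that("perfectly correlated pair has adjacency one", {
  set.seed(3)
  f <- rnorm(10)
  v <- rbind(a = f, b = f)
  colnames(v) <- paste0("s", 1:10)
  a <- adjacency_signed_hybrid(scale_genes(expr_matrix(v, "log10")))
  expect_equal(a["a", "b"], 1, tolerance = 1e-12)
})

test_that("TOM matches the hand-computed 3-node value and brute force", {
  a3 <- matrix(0, 3, 3)
  a3[1, 2] <- a3[2, 1] <- 1
  expect_equal(topological_overlap(a3)[1, 2], 1)

  expect_equal(max(abs(topological_overlap(matrix(0, 4, 4)) - diag(4))), 0)

  set.seed(4)
  for (i in 1:8) {
    n <- 15
    a <- matrix(runif(n * n, 0, 0.9), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_lt(max(abs(topological_overlap(a) - oracle_tom(a))), 1e-12)
  }

  bad <- matrix(runif(9), 3, 3)
  expect_error(topological_overlap(bad), "symmetric")
  a_neg <- matrix(0, 3, 3)
  a_neg[1, 2] <- a_neg[2, 1] <- -0.1
  expect_error(topological_overlap(a_neg), "\\[0, 1\\]")
})

test_that("TOM is a valid similarity and its dissimilarity well-formed", {
  set.seed(5)
  m <- scale_genes(rand_expr(30, 12, seed = 5))
  a <- adjacency_signed_hybrid(m)
  w <- topological_overlap(a)
  expect_true(all(w >= -1e-12 & w <= 1 + 1e-12))
  expect_lt(max(abs(w - t(w))), 1e-12)
  d <- tom_dissimilarity(a)
  expect_equal(diag(d), rep(0, 30), ignore_attr = TRUE)
  expect_true(all(d >= -1e-12))
})

test_that("planted blocks are recovered exactly and noise stays grey", {
  set.seed(6)
  n_s <- 20
  mk_block <- function(f, n) t(vapply(seq_len(n), function(i) {
    3 * f + rnorm(n_s)
  }, numeric(n_s)))
  f1 <- rnorm(n_s)
  f2 <- residuals(lm(rnorm(n_s) ~ f1)) # between-block correlation ~ 0
  v <- rbind(mk_block(f1, 50), mk_block(f2, 50),
             matrix(rnorm(100 * n_s), 100, n_s))
  dimnames(v) <- list(sprintf("g%03d", 1:200), paste0("s", 1:n_s))
  ms <- build_coexpression_modules(scale_genes(expr_matrix(v, "log10")))
  planted <- rep(c("A", "B", "none"), c(50, 50, 100))
  lab <- ms$labels$module
  non_grey <- setdiff(unique(lab[1:100]), "grey")
  expect_equal(length(non_grey), 2)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(planted[1:100], lab[1:100]), 0.95)
})

test_that("pure-noise matrices stay almost entirely unassigned", {
  greys <- vapply(1:10, function(s) {
    m <- scale_genes(rand_expr(250, 20, seed = 100 + s))
    mean(build_coexpression_modules(m)$labels$module == "grey")
  }, numeric(1))
  expect_true(all(greys >= 0.9))
})

test_that("blocks below the minimum module size stay grey", {
  set.seed(7)
  n_s <- 20
  f <- rnorm(n_s)
  small <- t(vapply(1:10, function(i) 3 * f + rnorm(n_s), numeric(n_s)))
  v <- rbind(small, matrix(rnorm(150 * n_s), 150, n_s))
  dimnames(v) <- list(sprintf("g%03d", 1:160), paste0("s", 1:n_s))
  ms <- build_coexpression_modules(scale_genes(expr_matrix(v, "log10")),
                                   network_params(min_module_size = 30))
  expect_true(all(ms$labels$module[1:10] == "grey"))
})

test_that("module detection is invariant to gene permutation", {
  set.seed(8)
  m <- scale_genes(rand_expr(120, 15, seed = 8))
  x <- unclass(m)
  f1 <- rnorm(15)
  f2 <- rnorm(15)
  x[1:40, ] <- t(vapply(1:40, function(i) 2 * f1 + rnorm(15), numeric(15)))
  x[41:80, ] <- t(vapply(1:40, function(i) 2 * f2 + rnorm(15), numeric(15)))
  m <- scale_genes(expr_matrix(x, "log10"))
  d <- tom_dissimilarity(adjacency_signed_hybrid(m))
  l1 <- detect_modules(d)
  perm <- sample(120)
  l2 <- detect_modules(d[perm, perm])
  merged <- dplyr::inner_join(l1, l2, by = "gene_id")
  tab <- table(merged$module.x, merged$module.y)
  # one-to-one label correspondence
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("eigengenes behave like first principal components", {
  set.seed(9)
  n_s <- 12
  f <- rnorm(n_s)
  v <- t(vapply(1:20, function(i) 2 * f + rnorm(n_s, 0, 0.5), numeric(n_s)))
  dimnames(v) <- list(sprintf("g%02d", 1:20), paste0("s", 1:n_s))
  m <- expr_matrix(v, "log10")
  labels <- tibble::tibble(gene_id = rownames(v), module = "blue")
  me <- module_eigengenes(m, labels)
  e <- me$eigengenes["blue", ]
  # correlates strongly with the planted factor, positively with members
  expect_gt(abs(cor(e, f)), 0.95)
  expect_gt(mean(cor(t(unclass(scale_genes(m))), e)), 0)
  # negating all members flips nothing thanks to the orientation rule
  me2 <- module_eigengenes(expr_matrix(-v, "log10"), labels)
  expect_gt(mean(cor(t(unclass(scale_genes(expr_matrix(-v, "log10")))),
                     me2$eigengenes["blue", ])), 0)
  # identical genes: eigengene correlates 1 with each member
  v_id <- matrix(rep(f, each = 5), 5, n_s,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:n_s)))
  me3 <- module_eigengenes(expr_matrix(v_id, "log10"),
                           tibble::tibble(gene_id = rownames(v_id),
                                          module = "red"))
  expect_equal(abs(cor(me3$eigengenes["red", ], f)), 1, tolerance = 1e-10)
  # singleton module flagged
  me4 <- module_eigengenes(m, tibble::tibble(gene_id = "g01", module = "tan"))
  expect_true(me4$singleton[["tan"]])
})

test_that("eigengene merging unites duplicated blocks and respects cut 0", {
  set.seed(10)
  n_s <- 16
  f1 <- rnorm(n_s)
  f2 <- rnorm(n_s)
  mk <- function(f, n, sd) t(vapply(seq_len(n), function(i) {
    2 * f + rnorm(n_s, 0, sd)
  }, numeric(n_s)))
  v <- rbind(mk(f1, 20, 0.3), mk(f1, 20, 0.3), mk(f2, 20, 0.3))
  dimnames(v) <- list(sprintf("g%02d", 1:60), paste0("s", 1:n_s))
  m <- expr_matrix(v, "log10")
  labels <- tibble::tibble(
    gene_id = rownames(v),
    module = rep(c("blue", "brown", "green"), each = 20)
  )
  merged <- merge_close_modules(m, labels, merge_cut = 0.15)
  expect_equal(merged$n_merges, 1L)
  expect_equal(length(unique(merged$labels$module)), 2)
  expect_equal(length(unique(merged$labels$module[1:40])), 1)
  # orthogonal blocks survive; merge_cut = 0 changes nothing
  untouched <- merge_close_modules(m, labels, merge_cut = 0)
  expect_equal(untouched$labels$module, labels$module)
})

test_that("module-trait correlation flags the planted trait module", {
  set.seed(11)
  n_s <- 20
  trait <- rep(c(0, 1), each = n_s / 2)
  e1 <- 0.8 * scale(trait)[, 1] + rnorm(n_s, 0, 0.4)
  e2 <- rnorm(n_s)
  me <- structure(
    list(eigengenes = rbind(blue = e1 / sqrt(sum(e1^2)),
                            red = e2 / sqrt(sum(e2^2)))),
    class = "module_eigengenes"
  )
  colnames(me$eigengenes) <- paste0("s", 1:n_s)
  out <- module_trait_correlation(me, data.frame(cond = trait))
  expect_gt(out$r[out$module == "blue"], 0.5)
  expect_lt(out$q[out$module == "blue"], 0.05)
  expect_gt(out$q[out$module == "red"], 0.05)
  # eigengene equal to the trait: r = 1
  me$eigengenes["red", ] <- scale(trait)[, 1] / sqrt(n_s - 1)
  out2 <- module_trait_correlation(me, data.frame(cond = trait))
  expect_equal(out2$r[out2$module == "red"], 1, tolerance = 1e-10)
  expect_error(
    module_trait_correlation(me, data.frame(cond = trait[1:5])),
    "one row per sample"
  )
})
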
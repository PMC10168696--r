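test_that("classification reproduces the printed concordance examples", {
  genes <- c("ELN", "BMP6", "TK1", "IDLE")
  drift <- fake_drift_table(
    gene_id = genes,
    t_stat = c(25.2, 22.0, -29.3, 1.0),
    q = c(9e-13, 8e-11, 1e-12, 0.5),
    drifted = c(TRUE, TRUE, TRUE, FALSE)
  )
  perturb <- fake_de(
    gene_id = genes,
    t_stat = c(8.3, -3.2, -4.0, 5.0),
    q = c(2e-2, 4.5e-2, 3e-2, 1e-3)
  )
  cl <- concordance_classify(drift, perturb)
  expect_equal(cl$category[cl$gene_id == "ELN"], "concordant_up")
  expect_equal(cl$category[cl$gene_id == "BMP6"], "discordant_up_down")
  expect_equal(cl$category[cl$gene_id == "TK1"], "concordant_down")
  expect_equal(cl$category[cl$gene_id == "IDLE"], "not_drifted")
  expect_true(all(cl$rescued == (cl$category %in%
                                   c("concordant_up", "concordant_down"))))

  # non-significant perturbation: drift_only regardless of sign
  perturb2 <- fake_de(genes, c(8.3, -3.2, -4.0, 5.0), q = rep(0.5, 4))
  cl2 <- concordance_classify(drift, perturb2)
  expect_equal(cl2$category[1:3], rep("drift_only", 3))
  expect_equal(cl2$category[4], "not_drifted")

  expect_error(concordance_classify(drift, fake_de("X", 1, 0.1)), "universe")
})

test_that("categories partition the universe and survive monotone rescaling", {
  set.seed(1)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  drift <- fake_drift_table(genes, rnorm(n, 0, 10),
                            q = runif(n), drifted = runif(n) < 0.4)
  perturb <- fake_de(genes, rnorm(n, 0, 5), q = runif(n))
  cl <- concordance_classify(drift, perturb)
  expect_equal(sort(table(cl$category)["not_drifted"][[1]]),
               sum(!drift$drifted))
  expect_equal(nrow(cl), n)
  # every gene in exactly one category
  expect_true(all(cl$category %in% c(
    "concordant_up", "concordant_down", "discordant_up_down",
    "discordant_down_up", "drift_only", "not_drifted"
  )))
  # gene order invariance
  perm <- sample(n)
  cl_perm <- concordance_classify(drift[perm, ], perturb)
  expect_equal(cl_perm$category[match(genes, cl_perm$gene_id)], cl$category)
  # rescaling t by a positive factor preserves the classification
  perturb3 <- perturb
  perturb3$t_stat <- perturb3$t_stat * 7
  expect_equal(concordance_classify(drift, perturb3)$category, cl$category)
})

test_that("rescue partition identity holds exactly under fuzzing", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(50:200, 1)
    genes <- sprintf("g%03d", 1:n)
    drift <- fake_drift_table(genes, rnorm(n, 0, 8), runif(n),
                              drifted = runif(n) < runif(1))
    c_f <- concordance_classify(drift, fake_de(genes, rnorm(n, 0, 4), runif(n)))
    c_c <- concordance_classify(drift, fake_de(genes, rnorm(n, 0, 4), runif(n)))
    pa <- rescue_fractions(c_f, c_c, drift)
    expect_equal(pa$n_flow_only + pa$n_cc_only + pa$n_both + pa$n_unrescued,
                 pa$n_drifted)
    expect_equal(pa$drifted,
                 pa$rescued_by_flow_only + pa$rescued_by_cc_only +
                   pa$rescued_by_both + pa$unrescued)
    expect_true(all(unlist(pa[, 9:17]) >= 0 & unlist(pa[, 9:17]) <= 1))
  }
})

test_that("no significant perturbation means zero rescue", {
  genes <- sprintf("g%02d", 1:50)
  drift <- fake_drift_table(genes, rnorm(50, 0, 6), runif(50, 0, 1e-3),
                            drifted = rep(TRUE, 50))
  c_f <- concordance_classify(drift, fake_de(genes, rnorm(50), rep(0.9, 50)))
  pa <- rescue_fractions(c_f, NULL, drift)
  expect_equal(pa$rescued_by_flow, 0)
  expect_equal(pa$unrescued, pa$drifted)
})

test_that("a classification from another drift table is rejected", {
  genes <- sprintf("g%02d", 1:20)
  d1 <- fake_drift_table(genes, rnorm(20), runif(20), runif(20) < 0.5)
  d2 <- fake_drift_table(genes, rnorm(20), runif(20), runif(20) < 0.5)
  c1 <- concordance_classify(d1, fake_de(genes, rnorm(20), runif(20)))
  expect_error(rescue_fractions(c1, NULL, d2), "different drift table")
})

test_that("time correlation is exact for identical and null inputs", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(3)
  de_c <- fake_de(genes, rnorm(200, 0, 5), runif(200))
  tc <- timecourse_correlation(de_c, list(`8` = de_c, `48` = de_c))
  expect_equal(tc$r, c(1, 1), tolerance = 1e-12)
  expect_equal(tc$timepoint_h, c(8, 48))

  null_r <- replicate(50, {
    de_n <- fake_de(genes, rnorm(200), runif(200))
    timecourse_correlation(de_c, list(`8` = de_n, `48` = de_n))$r[1]
  })
  expect_lt(abs(mean(null_r)), 2 / sqrt(200))

  expect_error(timecourse_correlation(de_c, list(`8` = de_c)), ">= 2")
  expect_error(
    timecourse_correlation(de_c[1:2, ], list(`8` = de_c[1:2, ], `48` = de_c[1:2, ])),
    "3 shared genes"
  )
})

test_that("cross-omic concordance matches matched-pair Pearson", {
  genes <- sprintf("g%03d", 1:100)
  prots <- paste0("PR_", genes)
  set.seed(4)
  t_rna <- rnorm(100, 0, 5)
  t_prot <- 0.4 * t_rna + rnorm(100, 0, 3)
  de_rna <- fake_de(genes, t_rna, runif(100))
  de_prot <- fake_de(prots, t_prot, runif(100))
  map <- tibble::tibble(gene_id = genes, protein_id = prots)
  out <- crossomic_concordance(de_rna, de_prot, map)
  expect_equal(out$r, cor(t_rna, t_prot), tolerance = 1e-12)
  expect_equal(out$n_matched, 100)

  # identical vectors give r = 1
  out1 <- crossomic_concordance(de_rna, fake_de(prots, t_rna, runif(100)), map)
  expect_equal(out1$r, 1, tolerance = 1e-12)

  # case-insensitive matching, unmatched ids counted
  map2 <- map
  map2$gene_id <- toupper(map2$gene_id)
  out2 <- crossomic_concordance(de_rna, de_prot, map2[1:40, ])
  expect_equal(out2$n_matched, 40)
  expect_equal(out2$n_unmatched_rna, 60)

  # swapped map columns cannot produce a spurious correlation
  swapped <- tibble::tibble(gene_id = prots, protein_id = genes)
  expect_error(crossomic_concordance(de_rna, de_prot, swapped), "zero matched")
})

test_that("gene-set score recovers a planted shift and centers at null", {
  p <- sim_params(n_genes = 800, pi_drift = 0, pi_flow_rescue = 0,
                  pi_cc_rescue = 0, n_modules = 0, noise_sd = 0.1,
                  batch_shift_sd = 0, seed = 5)
  st <- generate_study(p)
  x <- unclass(st$expr)
  cc <- st$samples$environment == "co_culture"
  set_genes <- rownames(x)[1:60]
  x[1:60, cc] <- x[1:60, cc] + 1
  m <- expr_matrix(x, "log10")
  sc <- geneset_module_score(m, set_genes, n_bins = 6, seed = 9)
  gap <- mean(sc$score[cc[match(sc$sample_id, st$samples$sample_id)]]) -
    mean(sc$score[st$samples$environment == "mono_culture"])
  expect_lt(abs(gap - 1), 0.1)

  # random set on null data: scores near zero
  null_scores <- vapply(1:5, function(s) {
    mean(geneset_module_score(st$expr, sample(rownames(x), 50),
                              n_bins = 6, seed = s)$score)
  }, numeric(1))
  expect_lt(abs(mean(null_scores)), 0.1)

  # deterministic given the seed
  s1 <- geneset_module_score(m, set_genes, n_bins = 6, seed = 3)
  s2 <- geneset_module_score(m, set_genes, n_bins = 6, seed = 3)
  expect_identical(s1, s2)

  expect_error(geneset_module_score(m, character(0)), "empty")
  expect_error(geneset_module_score(m, "not_a_gene"), "absent")
  expect_warning(geneset_module_score(m, set_genes, n_bins = 2,
                                      n_ctrl = 100000, seed = 1),
                 "replacement")
})
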
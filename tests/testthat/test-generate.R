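test_that("parameter validation names the offending field", {
  expect_error(sim_params(pi_drift = 1.2), "pi_drift")
  expect_error(sim_params(timepoints_h = c(0.5, 8)), "timepoints_h")
  expect_error(sim_params(timepoints_h = c(0, 8, 8)), "timepoints_h")
  expect_error(sim_params(n_genes = 100, n_modules = 5, module_size = 30),
               "sizing")
  expect_error(sim_params(pi_flow_rescue = 0.4, pi_cc_rescue = 0.2,
                          pi_drift = 0.43),
               "pi_flow_rescue")
})

test_that("identical seeds give bit-identical matrices and truth", {
  p <- sim_params(n_genes = 300, n_modules = 2, module_size = 40, seed = 11)
  a <- generate_study(p)
  b <- generate_study(p)
  expect_identical(unclass(a$expr), unclass(b$expr))
  expect_identical(a$truth, b$truth)
  ta <- generate_timecourse(p, a$truth)
  tb <- generate_timecourse(p, b$truth)
  expect_identical(unclass(ta$expr), unclass(tb$expr))
})

test_that("no planted effect means groups differ only by noise", {
  p <- sim_params(n_genes = 400, pi_drift = 0, pi_flow_rescue = 0,
                  pi_cc_rescue = 0, n_modules = 0, seed = 2)
  st <- generate_study(p)
  expect_true(all(st$truth$drift_direction == 0))
  smp <- st$samples
  cord <- rowMeans(unclass(st$expr)[, smp$environment == "cord"])
  cult <- rowMeans(unclass(st$expr)[, smp$environment != "cord"])
  # difference of group means of pure noise: se ~ noise_sd * sqrt(1/7+1/19)
  expect_lt(max(abs(cord - cult)), 6 * 0.5 * sqrt(1 / 7 + 1 / 19))
})

test_that("noiseless all-up limit: culture mean exceeds cord mean by delta", {
  p <- sim_params(n_genes = 200, pi_drift = 1, prob_up = 1,
                  pi_flow_rescue = 0, pi_cc_rescue = 0,
                  noise_sd = 0, batch_shift_sd = 0, culture_severity_sd = 0,
                  n_modules = 0, seed = 3)
  st <- generate_study(p)
  smp <- st$samples
  cord <- rowMeans(unclass(st$expr)[, smp$environment == "cord"])
  cult <- rowMeans(unclass(st$expr)[, smp$environment %in%
                                      c("early_culture", "late_culture")])
  expect_true(all(st$truth$drift_direction == 1))
  expect_equal(cult - cord, abs(st$truth$delta), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(cult > cord))
})

test_that("realized fractions sit within binomial error of requested", {
  fails <- 0
  for (s in 1:20) {
    tr <- generate_study(sim_params(n_genes = 5000, seed = s))$truth
    g <- glance(tr)
    tol <- function(p) 3 * sqrt(p * (1 - p) / 5000)
    ok <- abs(g$frac_drifted - 0.43) <= tol(0.43) &&
      abs(g$frac_flow_rescued - 0.17) <= tol(0.17) &&
      abs(g$frac_cc_rescued - 0.09) <= tol(0.09)
    fails <- fails + !ok
  }
  # 60 checks at ~0.3% tail mass each: a lone 3-sigma miss is expected
  expect_lte(fails, 1)
})

test_that("rescue flags imply drift and stay disjoint by default", {
  tr <- generate_study(sim_params(n_genes = 2000, seed = 5))$truth
  expect_true(all(tr$drift_direction[tr$flow_rescued] != 0))
  expect_true(all(tr$drift_direction[tr$cc_rescued] != 0))
  expect_false(any(tr$flow_rescued & tr$cc_rescued))
})

test_that("cord samples never carry drift or rescue terms", {
  p <- sim_params(n_genes = 300, noise_sd = 0, batch_shift_sd = 0,
                  culture_severity_sd = 0, n_modules = 0, seed = 7)
  st <- generate_study(p)
  cord_cols <- st$samples$environment == "cord"
  cord_vals <- unclass(st$expr)[, cord_cols]
  # all cord samples equal the gene baseline exactly
  expect_equal(max(apply(cord_vals, 1, function(r) diff(range(r)))), 0)
})

test_that("time-course rescue decays linearly to zero at the last timepoint", {
  p <- sim_params(n_genes = 300, noise_sd = 0, batch_shift_sd = 0,
                  culture_severity_sd = 0, n_modules = 0,
                  timepoints_h = c(0, 24, 48), seed = 8)
  st <- generate_study(p)
  tc <- generate_timecourse(p, st$truth)
  smp <- tc$samples
  base_cols <- which(smp$timepoint_h == 0)
  resc <- which(st$truth$flow_rescued)
  non_resc <- which(st$truth$drift_direction != 0 & !st$truth$flow_rescued &
                      !st$truth$cc_rescued)
  x <- unclass(tc$expr)
  for (h in c(24, 48)) {
    cols <- which(smp$timepoint_h == h)
    eff <- rowMeans(x[, cols, drop = FALSE]) -
      (rowMeans(x[, base_cols, drop = FALSE]) - st$truth$delta)
    expect_equal(eff[resc], st$truth$delta[resc] * (1 - h / 48),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(eff[non_resc], st$truth$delta[non_resc],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("noiseless planted effects tie cord-culture and flow-static axes", {
  p <- sim_params(n_genes = 500, noise_sd = 0, batch_shift_sd = 0,
                  culture_severity_sd = 0, n_modules = 0, seed = 9)
  st <- generate_study(p)
  tc <- generate_timecourse(p, st$truth)
  smp <- tc$samples
  x <- unclass(tc$expr)
  resc <- st$truth$flow_rescued
  flow48 <- rowMeans(x[, smp$timepoint_h == 48, drop = FALSE])
  static <- rowMeans(x[, smp$timepoint_h == 0, drop = FALSE])
  cord_effect <- -st$truth$delta # cord minus culture
  expect_equal(cor(cord_effect[resc], (flow48 - static)[resc]), 1,
               tolerance = 1e-12)
})

test_that("protein layer hits the target effect correlation", {
  p <- sim_params(n_genes = 2000, seed = 10)
  st <- generate_study(p)
  pl <- generate_protein_layer(p, st$truth)
  expect_equal(nrow(pl$id_map), sum(st$truth$protein_mapped))
  expect_true(all(rownames(pl$protein) == pl$id_map$protein_id))
  r <- cor(pl$effects$rna_delta, pl$effects$protein_delta)
  expect_gt(r, 0.3)
  expect_lt(r, 0.5)

  # rho = 1 reproduces the RNA effects up to scale
  p1 <- sim_params(n_genes = 2000, protein_rho = 1, seed = 10)
  st1 <- generate_study(p1)
  pl1 <- generate_protein_layer(p1, st1$truth)
  expect_equal(cor(pl1$effects$rna_delta, pl1$effects$protein_delta), 1,
               tolerance = 1e-12)

  # rho = 0: correlation within the null sampling bound
  p0 <- sim_params(n_genes = 2000, protein_rho = 0, seed = 10)
  st0 <- generate_study(p0)
  pl0 <- generate_protein_layer(p0, st0$truth)
  expect_lt(abs(cor(pl0$effects$rna_delta, pl0$effects$protein_delta)),
            2 / sqrt(nrow(pl0$effects)))
})

test_that("an empty protein layer is an explicit error", {
  p <- sim_params(n_genes = 100, n_modules = 0, protein_fraction = 0, seed = 1)
  st <- generate_study(p)
  expect_error(generate_protein_layer(p, st$truth), "empty protein layer")
})

test_that("truth lineage is enforced", {
  p1 <- sim_params(n_genes = 100, n_modules = 0, seed = 1)
  p2 <- sim_params(n_genes = 100, n_modules = 0, seed = 2)
  st <- generate_study(p1)
  expect_error(generate_timecourse(p2, st$truth), "truth")
  expect_error(generate_protein_layer(p2, st$truth), "truth")
})
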
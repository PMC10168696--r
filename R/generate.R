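#' Generate the synthetic multi-environment study
#'
#' Simulates the matched-donor study: a paired arm (each donor contributes a
#' cord, an early-culture and a late-culture sample) and a mono-/co-culture
#' arm, with planted ground truth per gene. The per-gene model on the log10
#' scale is
#'
#'   x_gs = b_g + lambda * f_m(g),s + delta_g * culture_s * (1 - rho_gs)
#'          + gamma_g,batch(s) + eps_gs
#'
#' where `delta_g = direction_g * |N(drift_effect_mean, drift_effect_sd)|` is
#' the planted culture drift (cord samples never carry it), `f_m,s` is the
#' latent factor of the gene's co-expression block (module 1's factor is tied
#' to the cord indicator), `rho_gs = 1` for co-culture-rescued genes in
#' co-culture samples (else 0 here), `gamma` are additive per-gene batch
#' effects centered to zero mean across batches, and `eps ~ N(0, noise_sd)`.
#'
#' Planted module genes are drawn from the non-drifted pool when it is large
#' enough, so the drift plant and the co-expression plant stay separable.
#'
#' @param params A [sim_params()] object.
#' @return A list with `expr` (an [expr_matrix()] on the log10 scale),
#'   `samples` (tibble: sample_id, donor, environment, timepoint_h, batch,
#'   layer), and `truth` (a `synthetic_truth` tibble: gene_id,
#'   drift_direction, delta, flow_rescued, cc_rescued, module_id,
#'   protein_mapped; realized fractions and the seed as attributes, see
#'   [glance.synthetic_truth()]).
#' @seealso [generate_timecourse()], [generate_protein_layer()]
#' @examples
#' st <- generate_study(sim_params(n_genes = 200, seed = 1))
#' glance(st$truth)
#' @export
generate_study <- function(params) {
  validate_sim_params(params)
  set.seed(gen_seed(params$seed, 0L))
  truth <- draw_truth(params)

  env_paired <- c("cord", "early_culture", "late_culture")
  samples <- dplyr::bind_rows(
    tidyr::expand_grid(
      donor = paste0("P", seq_len(params$donors_paired)),
      environment = env_paired
    ),
    tidyr::expand_grid(
      donor = paste0("C", seq_len(params$donors_cc)),
      environment = c("mono_culture", "co_culture")
    )
  )
  samples$sample_id <- paste(samples$donor, samples$environment, sep = "_")
  samples$timepoint_h <- NA_real_
  samples$batch <- assign_batches(samples$environment, params$n_batches)
  samples$layer <- "rna"
  samples <- samples[, c("sample_id", "donor", "environment", "timepoint_h",
                         "batch", "layer")]
  if (nrow(samples) == 0) abort("study design has no samples")

  culture <- as.numeric(samples$environment != "cord")
  # rescue attenuation: co-culture rescue acts fully in co_culture samples
  rho <- outer(
    truth$cc_rescued,
    samples$environment == "co_culture",
    FUN = function(g, s) as.numeric(g & s)
  )
  x <- build_expression(params, truth, samples, culture, rho,
                        cord_ind = samples$environment == "cord")
  list(expr = x, samples = as_tibble(samples), truth = truth)
}

#' Generate the flow time-course arm
#'
#' One sample per (flow donor, timepoint); the 0 h samples are the static
#' controls. All samples are cultured, so every drifted gene carries its full
#' effect except flow-rescued genes, whose culture effect decays linearly to
#' zero at the last timepoint: the planted effect at time t is
#' `delta * (1 - t / max(timepoints_h))`.
#'
#' @param params The [sim_params()] used for [generate_study()].
#' @param truth The `truth` table returned by [generate_study()] under the
#'   same seed lineage.
#' @return A list with `expr` (log10-scale [expr_matrix()]) and `samples`.
#' @examples
#' p <- sim_params(n_genes = 200, seed = 1)
#' st <- generate_study(p)
#' tc <- generate_timecourse(p, st$truth)
#' table(tc$samples$timepoint_h)
#' @export
generate_timecourse <- function(params, truth) {
  validate_sim_params(params)
  check_truth_lineage(params, truth)
  if (length(params$timepoints_h) == 0) {
    param_error("timepoints_h", "must contain at least one timepoint")
  }
  set.seed(gen_seed(params$seed, 1L))

  samples <- tidyr::expand_grid(
    donor = paste0("F", seq_len(params$donors_flow)),
    timepoint_h = params$timepoints_h
  )
  samples$environment <- ifelse(samples$timepoint_h == 0, "static", "flow")
  samples$sample_id <- paste0(samples$donor, "_t", samples$timepoint_h)
  samples$batch <- assign_batches(
    paste0("t", samples$timepoint_h), params$n_batches
  )
  samples$layer <- "rna"
  samples <- samples[, c("sample_id", "donor", "environment", "timepoint_h",
                         "batch", "layer")]
  if (nrow(samples) == 0) abort("flow arm has no samples")

  t_max <- max(params$timepoints_h)
  frac <- if (t_max > 0) samples$timepoint_h / t_max else rep(0, nrow(samples))
  rho <- outer(as.numeric(truth$flow_rescued), frac)
  culture <- rep(1, nrow(samples))
  x <- build_expression(params, truth, samples, culture, rho,
                        cord_ind = rep(FALSE, nrow(samples)))
  list(expr = x, samples = as_tibble(samples))
}

#' Generate the protein layer
#'
#' For each mapped gene the planted protein effect is
#' `delta'_g = rho * delta_g + sd(delta) * sqrt(1 - rho^2) * eta_g` with
#' `eta ~ N(0, 1)`, i.e. the RNA effect standardized, mixed with independent
#' noise at the target correlation `protein_rho`, and rescaled back to the
#' delta scale. Abundances are simulated for matched cord and early-culture
#' samples of the paired donors. Unmapped genes are absent from the matrix.
#'
#' @inheritParams generate_timecourse
#' @return A list with `protein` (linear-model log10 abundances,
#'   [expr_matrix()]), `id_map` (tibble gene_id, protein_id), `samples`
#'   (protein-layer sample table), and `effects` (tibble gene_id, protein_id,
#'   rna_delta, protein_delta — the planted truth for the mapped genes).
#' @examples
#' p <- sim_params(n_genes = 300, seed = 1)
#' st <- generate_study(p)
#' pl <- generate_protein_layer(p, st$truth)
#' nrow(pl$id_map)
#' @export
generate_protein_layer <- function(params, truth) {
  validate_sim_params(params)
  check_truth_lineage(params, truth)
  if (params$protein_fraction == 0 || !any(truth$protein_mapped)) {
    abort("empty protein layer: protein_fraction is 0 (no mapped genes)")
  }
  set.seed(gen_seed(params$seed, 2L))

  mapped <- which(truth$protein_mapped)
  delta <- truth$delta[mapped]
  sigma <- sd(delta)
  if (!is.finite(sigma)) sigma <- 0
  rho <- params$protein_rho
  eta <- rnorm(length(mapped))
  protein_delta <- rho * delta + sigma * sqrt(1 - rho^2) * eta

  id_map <- tibble(
    gene_id = truth$gene_id[mapped],
    protein_id = paste0("PR_", truth$gene_id[mapped])
  )
  samples <- tidyr::expand_grid(
    donor = paste0("P", seq_len(max(params$donors_paired, 1))),
    environment = c("cord", "early_culture")
  )
  samples$sample_id <- paste(samples$donor, "prot", samples$environment,
                             sep = "_")
  samples$timepoint_h <- NA_real_
  samples$batch <- "B1"
  samples$layer <- "protein"
  samples <- as_tibble(samples[, c("sample_id", "donor", "environment",
                                   "timepoint_h", "batch", "layer")])

  n_p <- length(mapped)
  n_s <- nrow(samples)
  baseline <- rnorm(n_p, params$baseline_mean, params$baseline_sd)
  culture <- as.numeric(samples$environment != "cord")
  vals <- matrix(baseline, n_p, n_s) +
    outer(protein_delta, culture) +
    matrix(rnorm(n_p * n_s, 0, params$protein_noise_sd), n_p, n_s)
  dimnames(vals) <- list(id_map$protein_id, samples$sample_id)

  list(
    protein = expr_matrix(vals, scale = "log10"),
    id_map = id_map,
    samples = samples,
    effects = tibble(
      gene_id = id_map$gene_id,
      protein_id = id_map$protein_id,
      rna_delta = delta,
      protein_delta = protein_delta
    )
  )
}

#' @describeIn generate_study One-row summary of the planted truth: realized
#'   drifted / flow-rescued / co-culture-rescued fractions (of all genes) and
#'   the seed.
#' @param x A `synthetic_truth` table.
#' @param ... Unused.
#' @export
glance.synthetic_truth <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    frac_drifted = mean(x$drift_direction != 0),
    frac_flow_rescued = mean(x$flow_rescued),
    frac_cc_rescued = mean(x$cc_rescued),
    frac_protein_mapped = mean(x$protein_mapped),
    n_module_genes = sum(!is.na(x$module_id)),
    seed = attr(x, "seed")
  )
}

# ---- internals --------------------------------------------------------------

gen_seed <- function(seed, stream) {
  as.integer((abs(seed) + 101 * stream) %% (.Machine$integer.max - 1L))
}

check_truth_lineage <- function(params, truth) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must come from generate_study()")
  }
  if (!identical(attr(truth, "seed"), params$seed) ||
      nrow(truth) != params$n_genes) {
    abort("`truth` was not produced by generate_study() with these params")
  }
  invisible(TRUE)
}

draw_truth <- function(params) {
  n <- params$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))

  drifted <- runif(n) < params$pi_drift
  direction <- integer(n)
  direction[drifted] <- ifelse(runif(sum(drifted)) < params$prob_up, 1L, -1L)
  delta <- numeric(n)
  delta[drifted] <- direction[drifted] *
    abs(rnorm(sum(drifted), params$drift_effect_mean, params$drift_effect_sd))

  flow_rescued <- cc_rescued <- logical(n)
  if (any(drifted) && params$pi_drift > 0) {
    pf <- min(1, params$pi_flow_rescue / params$pi_drift)
    pc <- min(1, params$pi_cc_rescue / params$pi_drift)
    if (params$rescue_overlap == 0) {
      u <- runif(sum(drifted))
      flow_rescued[drifted] <- u < pf
      cc_rescued[drifted] <- u >= pf & u < pf + pc
    } else {
      flow_rescued[drifted] <- runif(sum(drifted)) < pf
      cc_rescued[drifted] <- runif(sum(drifted)) < pc
    }
  }

  module_id <- rep(NA_character_, n)
  n_mod_genes <- params$n_modules * params$module_size
  if (n_mod_genes > 0) {
    pool <- which(!drifted)
    if (length(pool) < n_mod_genes) {
      # not enough quiet genes: fill the remainder from the drifted pool
      pool <- c(pool, sample(which(drifted)))
    }
    members <- pool[seq_len(n_mod_genes)]
    module_id[members] <- rep(
      paste0("M", seq_len(params$n_modules)),
      each = params$module_size
    )
  }

  protein_mapped <- runif(n) < params$protein_fraction

  truth <- tibble(
    gene_id = gene_id,
    drift_direction = direction,
    delta = delta,
    flow_rescued = flow_rescued,
    cc_rescued = cc_rescued,
    module_id = module_id,
    protein_mapped = protein_mapped
  )
  class(truth) <- c("synthetic_truth", class(truth))
  attr(truth, "seed") <- params$seed
  attr(truth, "realized") <- list(
    drift = mean(drifted),
    flow_rescue = mean(flow_rescued),
    cc_rescue = mean(cc_rescued)
  )
  truth
}

assign_batches <- function(groups, n_batches) {
  n_batches <- max(1L, n_batches)
  batch <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    batch[idx] <- rep_len(seq_len(n_batches), length(idx))
  }
  paste0("B", batch)
}

# per-gene per-batch additive effects, centered to zero mean across batches
draw_batch_effects <- function(n_genes, batch_labels, batch_shift_sd) {
  levels <- sort(unique(batch_labels))
  g <- matrix(rnorm(n_genes * length(levels), 0, batch_shift_sd),
              n_genes, length(levels))
  g <- g - rowMeans(g)
  colnames(g) <- levels
  g
}

# Per-sample latent factors of the planted modules. The raw Gaussian draws
# are orthogonalized in-sample (QR, against the intercept and the cord
# indicator) so chance collinearity between factors cannot blur the planted
# block structure; module 1 then adds its cord component explicitly.
module_factors <- function(params, samples, cord_ind) {
  k <- params$n_modules
  if (k == 0) return(NULL)
  n <- nrow(samples)
  f <- matrix(rnorm(k * n), k, n)
  has_contrast <- any(cord_ind) && any(!cord_ind)
  if (n >= k + 2 + has_contrast) {
    basis <- cbind(1, if (has_contrast) as.numeric(cord_ind), t(f))
    q <- qr.Q(qr(basis))[, -seq_len(1 + has_contrast), drop = FALSE]
    f <- t(apply(t(q), 1, function(v) v / sd(v)))
  }
  if (has_contrast) {
    ind <- as.numeric(cord_ind)
    ind <- (ind - mean(ind)) / sd(ind)
    f[1, ] <- sqrt(0.5) * ind + sqrt(0.5) * f[1, ]
  }
  f
}

build_expression <- function(params, truth, samples, culture, rho, cord_ind) {
  n <- params$n_genes
  n_s <- nrow(samples)
  baseline <- rnorm(n, params$baseline_mean, params$baseline_sd)
  x <- matrix(baseline, n, n_s)

  f <- module_factors(params, samples, cord_ind)
  if (!is.null(f)) {
    mod_idx <- which(!is.na(truth$module_id))
    m_of_g <- as.integer(sub("^M", "", truth$module_id[mod_idx]))
    x[mod_idx, ] <- x[mod_idx, ] +
      params$module_loading * f[m_of_g, , drop = FALSE]
  }

  severity <- culture
  if (params$culture_severity_sd > 0 && any(culture > 0)) {
    donors <- sort(unique(samples$donor))
    a_d <- setNames(1 + rnorm(length(donors), 0, params$culture_severity_sd),
                    donors)
    severity <- culture * a_d[samples$donor]
  }
  x <- x + outer(truth$delta, severity) * (1 - rho)

  if (params$batch_shift_sd > 0 && params$n_batches > 1) {
    gamma <- draw_batch_effects(n, samples$batch, params$batch_shift_sd)
    x <- x + gamma[, samples$batch, drop = FALSE]
  }
  if (params$noise_sd > 0) {
    x <- x + matrix(rnorm(n * n_s, 0, params$noise_sd), n, n_s)
  }
  dimnames(x) <- list(truth$gene_id, samples$sample_id)
  expr_matrix(x, scale = "log10")
}
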
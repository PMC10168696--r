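#' Synthetic study generator parameters
#'
#' Parameters of the synthetic multi-environment endothelial study. Defaults
#' reproduce the design the pipeline targets: 7 paired donors with matched
#' cord / early-culture / late-culture samples, 4 donors with static + flow
#' time courses at 0.5, 8, 24 and 48 h, a co-culture arm, 43% of genes
#' drifting in culture, 17% of all genes rescued by flow and 9% by co-culture
#' (converted internally to fractions of the drifted genes, disjoint by
#' default), block-correlated module structure, additive mean-zero batch
#' effects, and a protein layer whose per-gene effects correlate imperfectly
#' with the RNA effects.
#'
#' Expression is generated directly on the log10 scale (Gaussian noise);
#' [to_linear()] exports TPM-like values for testing the log transform.
#'
#' @param n_genes Number of genes.
#' @param donors_paired Donors in the matched cord/early/late arm.
#' @param donors_flow Donors in the static/flow arm.
#' @param donors_cc Donors in the mono-/co-culture arm.
#' @param timepoints_h Flow exposure times in hours, ascending, first entry 0
#'   (static control).
#' @param pi_drift Fraction of genes with a planted culture drift.
#' @param pi_flow_rescue,pi_cc_rescue Planted rescue fractions, expressed as
#'   fractions of ALL genes (the headline convention); converted internally to
#'   fractions of drifted genes. Must satisfy
#'   `pi_flow_rescue + pi_cc_rescue <= pi_drift` when `rescue_overlap = 0`.
#' @param rescue_overlap 0 (default) makes the flow- and co-culture-rescued
#'   sets disjoint; any value > 0 switches to independent Bernoulli draws so
#'   the sets overlap at their product rate (sensitivity analyses only).
#' @param drift_effect_mean,drift_effect_sd Mean and sd of the absolute drift
#'   effect |delta| in log10 units.
#' @param prob_up Probability that a drifted gene drifts upward in culture
#'   (direction +1); default 0.5.
#' @param culture_severity_sd Donor-level heterogeneity of culture
#'   adaptation: each donor d carries a multiplicative severity
#'   `a_d ~ N(1, culture_severity_sd)` applied to the drift effects of all
#'   its cultured samples (cord samples carry no drift terms). This
#'   emulates the inter-individual variability of the culture response;
#'   without it cultured samples would be implausibly identical in their
#'   drift magnitude. Because severity is a donor property, within-donor
#'   contrasts (flow vs static, co- vs mono-culture) keep their planted
#'   effects unscathed up to the donor mean.
#' @param n_modules,module_size,module_loading Planted co-expression block
#'   structure: number of blocks, genes per block, and loading on the
#'   per-sample latent factor. Module 1's factor is tied to the cord
#'   indicator so one module is cord-associated by construction.
#' @param noise_sd Residual sd in log10 units.
#' @param n_batches,batch_shift_sd Additive per-gene batch effects, mean-zero
#'   across batches; batches are assigned round-robin within each condition.
#' @param baseline_mean,baseline_sd Per-gene baseline log10 expression.
#' @param protein_rho Target correlation between RNA and protein planted
#'   effects.
#' @param protein_fraction Fraction of genes with a mapped protein.
#' @param protein_noise_sd Residual sd of the protein layer.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated `generator_params` list.
#' @examples
#' p <- sim_params(n_genes = 500, seed = 1)
#' p$pi_drift
#' @export
sim_params <- function(n_genes = 10000,
                       donors_paired = 7,
                       donors_flow = 4,
                       donors_cc = 6,
                       timepoints_h = c(0, 0.5, 8, 24, 48),
                       pi_drift = 0.43,
                       pi_flow_rescue = 0.17,
                       pi_cc_rescue = 0.09,
                       rescue_overlap = 0,
                       drift_effect_mean = 3,
                       drift_effect_sd = 0.5,
                       prob_up = 0.5,
                       culture_severity_sd = 0.15,
                       n_modules = 5,
                       module_size = 200,
                       module_loading = 1,
                       noise_sd = 0.5,
                       n_batches = 2,
                       batch_shift_sd = 0.2,
                       baseline_mean = 1.5,
                       baseline_sd = 0.5,
                       protein_rho = 0.4,
                       protein_fraction = 0.3,
                       protein_noise_sd = 0.5,
                       seed = 1) {
  p <- list(
    n_genes = n_genes, donors_paired = donors_paired,
    donors_flow = donors_flow, donors_cc = donors_cc,
    timepoints_h = timepoints_h, pi_drift = pi_drift,
    pi_flow_rescue = pi_flow_rescue, pi_cc_rescue = pi_cc_rescue,
    rescue_overlap = rescue_overlap,
    drift_effect_mean = drift_effect_mean, drift_effect_sd = drift_effect_sd,
    prob_up = prob_up, culture_severity_sd = culture_severity_sd,
    n_modules = n_modules, module_size = module_size,
    module_loading = module_loading, noise_sd = noise_sd,
    n_batches = n_batches, batch_shift_sd = batch_shift_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    protein_rho = protein_rho, protein_fraction = protein_fraction,
    protein_noise_sd = protein_noise_sd, seed = seed
  )
  validate_sim_params(p)
  structure(p, class = "generator_params")
}

param_error <- function(field, msg) {
  abort(paste0("invalid generator parameter `", field, "`: ", msg))
}

validate_sim_params <- function(p) {
  count_fields <- c(
    "n_genes", "donors_paired", "donors_flow", "donors_cc",
    "n_modules", "module_size", "n_batches"
  )
  for (f in count_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      param_error(f, "must be a single non-negative integer")
    }
  }
  for (f in c("pi_drift", "pi_flow_rescue", "pi_cc_rescue", "rescue_overlap",
              "protein_fraction", "prob_up")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      param_error(f, "must be a fraction in [0, 1]")
    }
  }
  if (p$pi_flow_rescue + p$pi_cc_rescue > 1) {
    param_error("pi_flow_rescue", "pi_flow_rescue + pi_cc_rescue must be <= 1")
  }
  if (p$rescue_overlap == 0 && p$pi_drift > 0 &&
      p$pi_flow_rescue + p$pi_cc_rescue > p$pi_drift + 1e-12) {
    param_error(
      "pi_flow_rescue",
      "disjoint rescue sets need pi_flow_rescue + pi_cc_rescue <= pi_drift"
    )
  }
  for (f in c("drift_effect_sd", "noise_sd", "batch_shift_sd", "baseline_sd",
              "culture_severity_sd",
              "protein_noise_sd", "module_loading", "drift_effect_mean")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || !is.finite(v)) {
      param_error(f, "must be a single non-negative number")
    }
  }
  if (!is.numeric(p$protein_rho) || abs(p$protein_rho) > 1) {
    param_error("protein_rho", "must lie in [-1, 1]")
  }
  tp <- p$timepoints_h
  if (length(tp) < 1 || any(tp < 0) || is.unsorted(tp, strictly = TRUE) ||
      tp[1] != 0) {
    param_error(
      "timepoints_h",
      "must be strictly ascending non-negative hours starting at 0"
    )
  }
  if (p$n_modules * p$module_size > p$n_genes) {
    abort(paste0(
      "sizing error: n_modules * module_size (",
      p$n_modules * p$module_size, ") exceeds n_genes (", p$n_genes, ")"
    ))
  }
  if (!is.numeric(p$seed) || length(p$seed) != 1 || !is.finite(p$seed)) {
    param_error("seed", "must be a single integer")
  }
  invisible(p)
}
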
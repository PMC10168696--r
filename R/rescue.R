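#' Sign-concordance rescue classification
#'
#' Classifies every gene by comparing the cord-vs-culture drift direction
#' with the response to an in-vitro perturbation (laminar flow or
#' smooth-muscle co-culture). "Cord UP" means higher in cord than in
#' culture; a perturbation is concordant (a rescue) when its significant
#' response moves cultured cells back toward the cord state, i.e. its
#' t-statistic has the same sign as the cord-vs-culture t-statistic.
#'
#' Categories: `concordant_up` (cord UP, perturbation UP), `concordant_down`,
#' `discordant_up_down`, `discordant_down_up`, `drift_only` (drifted but the
#' perturbation response is not significant), `not_drifted`.
#'
#' @param de_cord A `drift_table` from [drift_screen()] (cord vs culture).
#' @param de_perturb A contrast table from [de_contrast()] with the
#'   perturbation coded so positive t means up under perturbation
#'   (flow - static, co - mono). Must cover the same gene universe.
#' @param sig_level Significance level of the perturbation rule.
#' @param sig_rule `"fdr"` (default, `q < sig_level`) or `"p"`.
#' @return A `rescue_classification` tibble: gene_id, cord_t, cord_q,
#'   perturb_t, perturb_q, category, rescued; summary fractions as
#'   attributes (see [glance.rescue_classification()]).
#' @export
concordance_classify <- function(de_cord, de_perturb,
                                 sig_level = 0.05,
                                 sig_rule = c("fdr", "p")) {
  sig_rule <- match.arg(sig_rule)
  if (!inherits(de_cord, "drift_table")) {
    abort("`de_cord` must be a drift_table from drift_screen().")
  }
  if (!setequal(de_cord$gene_id, de_perturb$gene_id)) {
    abort("gene universes of the two DE sets do not match.")
  }
  pe <- de_perturb[match(de_cord$gene_id, de_perturb$gene_id), , drop = FALSE]
  sig <- if (sig_rule == "fdr") pe$q < sig_level else pe$p < sig_level

  category <- dplyr::case_when(
    !de_cord$drifted ~ "not_drifted",
    !sig ~ "drift_only",
    de_cord$t_stat > 0 & pe$t_stat > 0 ~ "concordant_up",
    de_cord$t_stat < 0 & pe$t_stat < 0 ~ "concordant_down",
    de_cord$t_stat > 0 & pe$t_stat < 0 ~ "discordant_up_down",
    de_cord$t_stat < 0 & pe$t_stat > 0 ~ "discordant_down_up",
    TRUE ~ "drift_only" # zero statistics carry no direction
  )
  rescued <- category %in% c("concordant_up", "concordant_down")

  out <- tibble(
    gene_id = de_cord$gene_id,
    cord_t = de_cord$t_stat, cord_q = de_cord$q,
    perturb_t = pe$t_stat, perturb_q = pe$q,
    category = category, rescued = rescued
  )
  class(out) <- c("rescue_classification", class(out))
  drift_summary <- attr(de_cord, "summary")
  attr(out, "summary") <- list(
    n_expressed = drift_summary$n_expressed,
    n_drifted = drift_summary$n_drifted,
    n_rescued = sum(rescued),
    sig_level = sig_level, sig_rule = sig_rule,
    drifted_genes = de_cord$gene_id[de_cord$drifted]
  )
  out
}

#' @describeIn concordance_classify Category counts and rescue fractions
#'   (denominator: expressed genes) as a one-row tibble.
#' @param x A `rescue_classification`.
#' @param ... Unused.
#' @export
glance.rescue_classification <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(
    n_expressed = s$n_expressed,
    n_drifted = s$n_drifted,
    n_rescued = s$n_rescued,
    fraction_drifted = s$n_drifted / s$n_expressed,
    fraction_rescued = s$n_rescued / s$n_expressed,
    fraction_rescued_of_drifted = ifelse(s$n_drifted > 0,
                                         s$n_rescued / s$n_drifted, 0)
  )
}

#' Transcriptome partition into drifted / rescued / unrescued fractions
#'
#' Combines the flow and (optionally) co-culture rescue classifications
#' built on the same drift screen into the headline partition. All fractions
#' use the expressed-gene denominator; the identity
#' `drifted = flow_only + cc_only + both + unrescued` holds exactly by
#' construction. Fractions of the drifted genes are reported alongside.
#'
#' @param c_flow A `rescue_classification` for the flow perturbation.
#' @param c_cc Optional `rescue_classification` for co-culture.
#' @param drift The `drift_table` both classifications were built on.
#' @return A `rescue_partition` one-row tibble with counts and fractions.
#' @export
rescue_fractions <- function(c_flow, c_cc = NULL, drift) {
  s <- attr(drift, "summary")
  drifted_genes <- drift$gene_id[drift$drifted]
  check_same_drift <- function(cl, label) {
    if (!setequal(attr(cl, "summary")$drifted_genes, drifted_genes)) {
      abort(paste0("`", label, "` was built from a different drift table."))
    }
  }
  check_same_drift(c_flow, "c_flow")
  flow_set <- c_flow$gene_id[c_flow$rescued]
  if (!is.null(c_cc)) {
    check_same_drift(c_cc, "c_cc")
    cc_set <- c_cc$gene_id[c_cc$rescued]
  } else {
    cc_set <- character(0)
  }

  n_exp <- s$n_expressed
  n_drift <- length(drifted_genes)
  n_both <- length(intersect(flow_set, cc_set))
  n_flow_only <- length(setdiff(flow_set, cc_set))
  n_cc_only <- length(setdiff(cc_set, flow_set))
  n_either <- n_flow_only + n_cc_only + n_both
  n_unrescued <- n_drift - n_either

  out <- tibble(
    n_expressed = n_exp,
    n_drifted = n_drift,
    n_rescued_flow = length(flow_set),
    n_rescued_cc = length(cc_set),
    n_flow_only = n_flow_only,
    n_cc_only = n_cc_only,
    n_both = n_both,
    n_unrescued = n_unrescued,
    drifted = n_drift / n_exp,
    rescued_by_flow = length(flow_set) / n_exp,
    rescued_by_cc = length(cc_set) / n_exp,
    rescued_by_flow_only = n_flow_only / n_exp,
    rescued_by_cc_only = n_cc_only / n_exp,
    rescued_by_both = n_both / n_exp,
    rescued_by_either = n_either / n_exp,
    unrescued = n_unrescued / n_exp,
    flow_of_drifted = ifelse(n_drift > 0, length(flow_set) / n_drift, 0),
    cc_of_drifted = ifelse(n_drift > 0, length(cc_set) / n_drift, 0)
  )
  class(out) <- c("rescue_partition", class(out))
  out
}

#' Correlation-to-cord along the flow time course
#'
#' For each flow exposure time, the Pearson correlation across genes between
#' the cord-vs-culture statistic and the flow(t)-vs-static statistic. Under
#' progressive rescue this correlation rises with time under flow.
#'
#' @param de_cord A `drift_table` or [de_contrast()] tibble (cord vs
#'   culture).
#' @param de_flow Named list of [de_contrast()] tibbles, one per timepoint
#'   (names are hours), each flow(t) vs static.
#' @param stat `"t"` (default) or `"delta"`: which column to correlate.
#' @return A `time_correlation` tibble: timepoint_h, r, p, n_genes.
#' @export
timecourse_correlation <- function(de_cord, de_flow, stat = c("t", "delta")) {
  stat <- match.arg(stat)
  if (length(de_flow) < 2) abort("need >= 2 timepoints.")
  hours <- as.numeric(names(de_flow))
  if (any(is.na(hours))) abort("`de_flow` must be named by timepoint hours.")
  ord <- order(hours)
  col <- if (stat == "t") "t_stat" else "delta"

  rows <- purrr::map2_dfr(de_flow[ord], hours[ord], function(de_t, h) {
    shared <- intersect(de_cord$gene_id, de_t$gene_id)
    if (length(shared) < 3) abort("fewer than 3 shared genes.")
    a <- de_cord[[col]][match(shared, de_cord$gene_id)]
    b <- de_t[[col]][match(shared, de_t$gene_id)]
    ok <- is.finite(a) & is.finite(b)
    r <- cor(a[ok], b[ok])
    tibble(timepoint_h = h, r = r,
           p = cor_t_pvalue(r, sum(ok)), n_genes = sum(ok))
  })
  class(rows) <- c("time_correlation", class(rows))
  rows
}

#' @describeIn timecourse_correlation Line plot of r against hours of flow.
#' @param object A `time_correlation`.
#' @param ... Unused.
#' @export
autoplot.time_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timepoint_h, y = .data$r)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time under flow (h)",
                  y = "correlation to cord signature") +
    ggplot2::theme_minimal()
}

#' RNA-protein concordance of differential statistics
#'
#' Pearson correlation of matched t-statistics across the two -omic layers.
#' Matching is by gene symbol through the id map, case-insensitive;
#' unmatched ids are counted and reported, never silently dropped.
#'
#' @param de_rna DE tibble with `gene_id` and `t_stat`.
#' @param de_protein DE tibble with `gene_id` (protein ids) and `t_stat`.
#' @param id_map Two-column tibble `gene_id`, `protein_id`.
#' @return One-row tibble: r, p, n_matched, n_unmatched_rna,
#'   n_unmatched_protein.
#' @export
crossomic_concordance <- function(de_rna, de_protein, id_map) {
  if (!all(c("gene_id", "protein_id") %in% names(id_map))) {
    abort("`id_map` must have columns gene_id and protein_id.")
  }
  map_gene <- tolower(id_map$gene_id)
  map_prot <- tolower(id_map$protein_id)
  i_rna <- match(map_gene, tolower(de_rna$gene_id))
  i_prot <- match(map_prot, tolower(de_protein$gene_id))
  ok <- !is.na(i_rna) & !is.na(i_prot)
  if (sum(ok) == 0) {
    abort("id map yields zero matched gene-protein pairs.")
  }
  if (sum(ok) < 3) abort("id map yields fewer than 3 matched pairs.")
  a <- de_rna$t_stat[i_rna[ok]]
  b <- de_protein$t_stat[i_prot[ok]]
  fin <- is.finite(a) & is.finite(b)
  r <- cor(a[fin], b[fin])
  tibble(
    r = r,
    p = cor_t_pvalue(r, sum(fin)),
    n_matched = sum(fin),
    n_unmatched_rna = sum(!tolower(de_rna$gene_id) %in% map_gene),
    n_unmatched_protein = sum(!tolower(de_protein$gene_id) %in% map_prot)
  )
}

#' Expression-bin-matched gene-set score
#'
#' Per-sample score of a gene set against expression-matched controls: genes
#' are binned by average expression into `n_bins` quantile bins computed on
#' the set-excluded universe; for each set gene, `n_ctrl` control genes are
#' drawn (seeded) from its bin, and the score is the mean expression of the
#' set genes minus the mean expression of the drawn controls.
#'
#' @param m An [expr_matrix()].
#' @param gene_set Character vector of gene ids, all present in `m`.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100); bins
#'   smaller than `n_ctrl` are sampled with replacement with a warning.
#' @param seed Seed for the control draws.
#' @return Tibble: sample_id, score.
#' @export
geneset_module_score <- function(m, gene_set, n_bins = 24, n_ctrl = 100,
                                 seed = 1) {
  if (length(gene_set) == 0) abort("`gene_set` is empty.")
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing)) {
    abort(paste0("gene_set members absent from the matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  x <- unclass(m)
  avg <- rowMeans(x)
  in_set <- rownames(x) %in% gene_set

  pool_idx <- which(!in_set)
  if (length(pool_idx) == 0) {
    # degenerate: the set is the whole universe; controls come from the set
    pool_idx <- which(in_set)
  }
  breaks <- quantile(avg[pool_idx], probs = seq(0, 1, length.out = n_bins + 1))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  bin_of <- function(v) findInterval(v, breaks, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  pool_bins <- split(pool_idx, bin_of(avg[pool_idx]))

  set.seed(gen_seed(seed, 3L))
  set_idx <- which(in_set)
  n_short <- 0L
  ctrl_idx <- unlist(lapply(set_idx, function(g) {
    b <- as.character(bin_of(avg[g]))
    pool <- pool_bins[[b]]
    if (is.null(pool) || length(pool) == 0) pool <- pool_idx
    if (length(pool) < n_ctrl) n_short <<- n_short + 1L
    pool[sample.int(length(pool), n_ctrl, replace = length(pool) < n_ctrl)]
  }))
  if (n_short > 0) {
    warn(paste0(n_short, " set gene(s) sit in bins smaller than n_ctrl = ",
                n_ctrl, "; controls sampled with replacement"))
  }

  score <- colMeans(x[set_idx, , drop = FALSE]) -
    colMeans(x[ctrl_idx, , drop = FALSE])
  tibble(sample_id = colnames(x), score = unname(score))
}
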
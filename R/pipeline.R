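#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: either generator
#' parameters (synthetic mode) or paths to an expression TSV and sample
#' table, plus the thresholds and stage toggles.
#'
#' @param params A [sim_params()] object (synthetic mode), or NULL to read
#'   from files.
#' @param expression_path,samples_path Input files when `params` is NULL.
#' @param expression_scale Declared scale of the stored expression values.
#' @param out_dir Output directory for artifacts (created if absent); NULL
#'   disables writing.
#' @param drift_rule,alpha Drift significance rule and level (see
#'   [drift_screen()]).
#' @param sig_level Perturbation significance level for the rescue
#'   classification.
#' @param network A [network_params()] object, or NULL to skip the
#'   co-expression stage.
#' @param max_network_genes Cap on genes entering the network stage (most
#'   variable genes first); keeps the TOM computation tractable.
#' @param seed Seed recorded in every artifact and used for seeded stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(params = NULL,
                            expression_path = NULL, samples_path = NULL,
                            expression_scale = "linear",
                            out_dir = NULL,
                            drift_rule = "bonferroni", alpha = 0.05,
                            sig_level = 0.05,
                            network = network_params(),
                            max_network_genes = 2000,
                            seed = 1) {
  if (is.null(params)) {
    if (is.null(expression_path) || is.null(samples_path)) {
      abort("either `params` or both input paths must be given.")
    }
    for (p in c(expression_path, samples_path)) {
      if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
    }
  } else {
    validate_sim_params(params)
  }
  if (!drift_rule %in% c("bonferroni", "fdr")) {
    abort("`drift_rule` must be 'bonferroni' or 'fdr'.")
  }
  structure(
    list(params = params, expression_path = expression_path,
         samples_path = samples_path, expression_scale = expression_scale,
         out_dir = out_dir, drift_rule = drift_rule, alpha = alpha,
         sig_level = sig_level, network = network,
         max_network_genes = max_network_genes, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full drift-and-rescue pipeline
#'
#' Chains the stages end to end: simulate (or read) -> preprocess (log10 +
#' empirical-Bayes batch adjustment) -> drift screen -> rescue
#' classification and partition -> time-course correlation -> cross-omic
#' concordance -> co-expression modules -> time profiles. Per-gene tables
#' are written to `out_dir` (TSV, `#`-header with version and seed) and the
#' stage summaries are returned as a run report; every report number is
#' recomputable from the emitted tables.
#'
#' @param config A [pipeline_config()] object.
#' @return A `run_report` list: `drift` (glance), `partition`,
#'   `time_correlation`, `crossomic`, `modules` (glance), `config` echo and
#'   package version, plus the underlying result objects in `$results`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  synthetic <- !is.null(config$params)
  if (synthetic) {
    p <- config$params
    study <- stage("simulate", generate_study(p))
    tc <- stage("simulate", generate_timecourse(p, study$truth))
    prot <- if (p$protein_fraction > 0) {
      stage("simulate", generate_protein_layer(p, study$truth))
    }
    expr <- study$expr
    samples <- study$samples
  } else {
    expr <- stage("read", read_expression(
      config$expression_path, scale = config$expression_scale
    ))
    samples <- stage("read", read_sample_table(config$samples_path))
    tc <- NULL
    prot <- NULL
  }

  if (expr_scale(expr) == "linear") {
    expr <- stage("preprocess", log_transform(expr))
  }
  smp <- samples_for(expr, samples)
  if (length(unique(smp$batch)) > 1) {
    expr <- stage("preprocess", eb_batch_adjust(expr, smp$batch))
  }

  drift <- stage("drift", drift_screen(
    expr, samples, rule = config$drift_rule, alpha = config$alpha
  ))

  partition <- NULL
  c_flow <- c_cc <- NULL
  time_cor <- NULL
  profiles <- NULL
  if (!is.null(tc)) {
    tc_expr <- tc$expr
    tc_smp <- tc$samples
    if (length(unique(tc_smp$batch)) > 1) {
      tc_expr <- stage("preprocess", eb_batch_adjust(tc_expr, tc_smp$batch))
    }
    hours <- sort(setdiff(unique(tc_smp$timepoint_h), 0))
    de_flow <- lapply(hours, function(h) {
      sel <- tc_smp$timepoint_h %in% c(0, h)
      sub <- expr_matrix(unclass(tc_expr)[, sel, drop = FALSE],
                         expr_scale(tc_expr))
      smp_h <- tc_smp[sel, ]
      smp_h$environment <- ifelse(smp_h$timepoint_h == 0, "static", "flow")
      de_contrast(sub, smp_h, "flow", "static")
    })
    names(de_flow) <- hours
    c_flow <- stage("rescue", concordance_classify(
      drift, de_flow[[length(de_flow)]], sig_level = config$sig_level
    ))
    if (any(smp$environment == "co_culture")) {
      de_cc <- stage("rescue", de_contrast(
        expr, samples, "co_culture", "mono_culture"
      ))
      c_cc <- stage("rescue", concordance_classify(
        drift, de_cc, sig_level = config$sig_level
      ))
    }
    partition <- stage("rescue", rescue_fractions(c_flow, c_cc, drift))
    time_cor <- stage("rescue", timecourse_correlation(drift, de_flow))
    profiles <- stage("profiles", build_profiles(tc_expr, tc_smp))
  }

  crossomic <- NULL
  if (!is.null(prot)) {
    de_prot <- stage("crossomic", de_contrast(
      prot$protein, prot$samples, "early_culture", "cord"
    ))
    # orient both layers as cord-vs-culture
    de_prot$t_stat <- -de_prot$t_stat
    crossomic <- stage("crossomic", crossomic_concordance(
      drift, de_prot, prot$id_map
    ))
  }

  modules <- NULL
  if (!is.null(config$network)) {
    x <- unclass(expr)
    keep <- order(-apply(x, 1, var))
    keep <- sort(head(keep, config$max_network_genes))
    sub <- expr_matrix(x[keep, , drop = FALSE], expr_scale(expr))
    traits <- tibble(
      sample_id = smp$sample_id,
      cord = as.numeric(smp$environment == "cord")
    )
    modules <- stage("coexpression", build_coexpression_modules(
      scale_genes(sub), config$network, traits = traits
    ))
  }

  report <- structure(
    list(
      version = as.character(utils::packageVersion("driftrescue")),
      seed = config$seed,
      synthetic = synthetic,
      drift = glance(drift),
      partition = partition,
      time_correlation = time_cor,
      crossomic = crossomic,
      modules = if (!is.null(modules)) glance(modules),
      results = list(
        drift = drift, c_flow = c_flow, c_cc = c_cc,
        modules = modules, profiles = profiles
      )
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) {
    write_report_artifacts(report, config)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> driftrescue v", x$version, ", seed ", x$seed, "\n",
      sep = "")
  cat("drift: ", x$drift$n_drifted, "/", x$drift$n_expressed,
      " genes (", round(100 * x$drift$fraction_drifted, 1), "%)\n", sep = "")
  if (!is.null(x$partition)) {
    cat("rescued by flow ", round(100 * x$partition$rescued_by_flow, 1),
        "%, by co-culture ", round(100 * x$partition$rescued_by_cc, 1),
        "%, unrescued ", round(100 * x$partition$unrescued, 1), "%\n",
        sep = "")
  }
  invisible(x)
}

write_report_artifacts <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- paste0("# driftrescue v", report$version, " seed=", config$seed)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_lines(header, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  res <- report$results
  emit(as_tibble(res$drift), "drift_table.tsv")
  if (!is.null(res$c_flow)) {
    emit(as_tibble(res$c_flow), "rescue_flow.tsv")
    top <- dplyr::arrange(
      dplyr::filter(as_tibble(res$c_flow),
                    .data$category != "not_drifted"),
      .data$cord_q
    )
    emit(head(top, 30), "rescue_top30.tsv")
  }
  if (!is.null(res$c_cc)) emit(as_tibble(res$c_cc), "rescue_cc.tsv")
  if (!is.null(report$time_correlation)) {
    emit(as_tibble(report$time_correlation), "time_correlation.tsv")
  }
  if (!is.null(res$modules)) {
    emit(res$modules$labels, "module_labels.tsv")
    if (!is.null(res$modules$eigengenes)) {
      eig <- res$modules$eigengenes$eigengenes
      emit(dplyr::bind_cols(tibble(module = rownames(eig)), as_tibble(eig)),
           "module_eigengenes.tsv")
    }
    if (!is.null(res$modules$trait_cor)) {
      emit(res$modules$trait_cor, "module_trait_correlation.tsv")
    }
  }
  if (!is.null(res$profiles)) {
    export_profile_table(res$profiles,
                         file.path(config$out_dir, "profiles.tsv"))
  }
  summary <- list(
    version = report$version, seed = report$seed,
    drift = report$drift,
    partition = report$partition,
    time_correlation = report$time_correlation,
    crossomic = report$crossomic,
    modules = report$modules
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
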
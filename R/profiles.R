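#' Per-gene flow time-course profiles
#'
#' For every gene and timepoint, the arithmetic mean over all available
#' samples at that timepoint (static samples sit at t = 0), plus the
#' ordinary-least-squares intercept ("origin") and slope per hour of the
#' averages regressed on time.
#'
#' @param m An [expr_matrix()] of the flow-arm samples.
#' @param samples Sample table; rows matching the matrix columns must carry
#'   `timepoint_h` (samples with a missing timepoint are dropped with a
#'   warning, never imputed).
#' @return A `time_profiles` object: `averages` (gene x timepoint matrix),
#'   `timepoints_h`, `origin`, `slope`, `n_samples` per timepoint.
#' @export
build_profiles <- function(m, samples) {
  smp <- samples_for(m, samples)
  has_t <- is.finite(smp$timepoint_h)
  if (!any(has_t)) abort("no samples carry a timepoint_h.")
  if (any(!has_t)) {
    warn(paste0(sum(!has_t), " sample(s) without timepoint_h dropped"))
  }
  x <- unclass(m)[, has_t, drop = FALSE]
  tp <- smp$timepoint_h[has_t]
  times <- sort(unique(tp))
  averages <- vapply(times, function(t) {
    rowMeans(x[, tp == t, drop = FALSE])
  }, numeric(nrow(x)))
  if (!is.matrix(averages)) averages <- matrix(averages, nrow = nrow(x))
  dimnames(averages) <- list(rownames(x), paste0("t", times))
  reg <- profile_regression_matrix(averages, times)
  structure(
    list(averages = averages, timepoints_h = times,
         origin = reg$origin, slope = reg$slope,
         n_samples = vapply(times, function(t) sum(tp == t), integer(1))),
    class = "time_profiles"
  )
}

#' Origin and slope of a time profile
#'
#' Ordinary least squares of the per-timepoint averages on time in hours:
#' `origin` is the intercept at t = 0, `slope` the change per hour.
#'
#' @param averages Numeric vector of per-timepoint averages.
#' @param timepoints_h Matching hours (>= 2 distinct values).
#' @return List with `origin` and `slope`.
#' @examples
#' profile_regression(c(0, 48), c(0, 48)) # origin 0, slope 1
#' @export
profile_regression <- function(averages, timepoints_h) {
  if (length(averages) != length(timepoints_h)) {
    abort("averages and timepoints must have equal length.")
  }
  if (length(unique(timepoints_h)) < 2) {
    abort("regression needs >= 2 distinct timepoints.")
  }
  reg <- profile_regression_matrix(matrix(averages, nrow = 1), timepoints_h)
  list(origin = unname(reg$origin), slope = unname(reg$slope))
}

profile_regression_matrix <- function(avg, times) {
  if (length(unique(times)) < 2) {
    return(list(origin = avg[, 1], slope = rep(NA_real_, nrow(avg))))
  }
  tc <- times - mean(times)
  slope <- as.vector(avg %*% tc) / sum(tc^2)
  origin <- rowMeans(avg) - slope * mean(times)
  list(origin = origin, slope = slope)
}

#' Profile similarity and divergence search
#'
#' A reference profile plus a similarity value `s` in `[0, 2]` define a band
#' `[ref_t - s, ref_t + s]` at every timepoint. `similarity_search()`
#' returns genes whose averages lie inside the band at EVERY timepoint
#' (inclusive bounds); `divergence_search()` returns genes outside the band
#' at every timepoint by default (`match_all = FALSE` relaxes divergence to
#' any timepoint outside).
#'
#' The reference can be a gene id, several gene ids (their unweighted mean
#' profile is used), or an explicit per-timepoint numeric vector.
#'
#' @param profiles A [build_profiles()] object.
#' @param reference Gene id(s) present in the profiles, or a numeric vector
#'   with one value per timepoint.
#' @param s Similarity value in `[0, 2]`.
#' @param match_all Divergence convention: all timepoints outside (default)
#'   or any.
#' @return Character vector of matching gene ids.
#' @export
similarity_search <- function(profiles, reference, s) {
  band <- query_band(profiles, reference, s)
  dev <- abs(profiles$averages - matrix(band$ref, nrow(profiles$averages),
                                        length(band$ref), byrow = TRUE))
  rownames(profiles$averages)[rowSums(dev <= s) == ncol(profiles$averages)]
}

#' @rdname similarity_search
#' @export
divergence_search <- function(profiles, reference, s, match_all = TRUE) {
  band <- query_band(profiles, reference, s)
  dev <- abs(profiles$averages - matrix(band$ref, nrow(profiles$averages),
                                        length(band$ref), byrow = TRUE))
  outside <- dev > s
  hits <- if (match_all) {
    rowSums(outside) == ncol(profiles$averages)
  } else {
    rowSums(outside) > 0
  }
  rownames(profiles$averages)[hits]
}

query_band <- function(profiles, reference, s) {
  if (!is.numeric(s) || length(s) != 1 || s < 0 || s > 2) {
    abort("similarity value `s` must lie in [0, 2].")
  }
  if (is.character(reference)) {
    missing <- setdiff(reference, rownames(profiles$averages))
    if (length(missing)) {
      abort(paste0("reference gene(s) not in profiles: ",
                   paste(head(missing, 3), collapse = ", ")))
    }
    ref <- colMeans(profiles$averages[reference, , drop = FALSE])
  } else if (is.numeric(reference)) {
    if (length(reference) != length(profiles$timepoints_h)) {
      abort("numeric reference must cover every timepoint.")
    }
    ref <- as.numeric(reference)
  } else {
    abort("`reference` must be gene id(s) or a numeric profile.")
  }
  list(ref = ref, s = s)
}

#' Profile table export
#'
#' One row per gene: the per-timepoint averages plus the regression origin
#' and slope, in stable column order — the searchable table behind the
#' time-course browser.
#'
#' @param profiles A [build_profiles()] object.
#' @param path Optional file path; `.json` writes JSON, anything else TSV.
#' @return The wide tibble (invisibly when writing to a file).
#' @export
export_profile_table <- function(profiles, path = NULL) {
  if (nrow(profiles$averages) == 0) abort("no profiles to export.")
  out <- as_tibble(profiles$averages)
  out <- dplyr::bind_cols(
    tibble(gene_id = rownames(profiles$averages)), out,
    tibble(origin = unname(profiles$origin), slope = unname(profiles$slope))
  )
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(out, path, digits = NA, dataframe = "rows")
    } else {
      readr::write_tsv(out, path)
    }
    return(invisible(out))
  }
  out
}

#' @describeIn build_profiles Long tibble (gene_id, timepoint_h, average,
#'   origin, slope).
#' @param x A `time_profiles` object.
#' @param ... Unused.
#' @export
tidy.time_profiles <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$averages), times = length(x$timepoints_h)),
    timepoint_h = rep(x$timepoints_h, each = nrow(x$averages)),
    average = as.vector(x$averages),
    origin = rep(unname(x$origin), times = length(x$timepoints_h)),
    slope = rep(unname(x$slope), times = length(x$timepoints_h))
  )
}

#' @describeIn build_profiles Plot selected gene profiles over time.
#' @param object A `time_profiles` object.
#' @param genes Gene ids to draw.
#' @export
plot_profiles <- function(object, genes = head(rownames(object$averages), 5)) {
  df <- tidy.time_profiles(object)
  df <- df[df$gene_id %in% genes, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_h, y = .data$average,
                                   color = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time under flow (h)", y = "average expression",
                  color = "gene") +
    ggplot2::theme_minimal()
}
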
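#' Co-expression network parameters
#'
#' Settings of the signed-hybrid weighted co-expression analysis. The
#' soft-threshold power defaults to 3 and the network type is signed hybrid
#' (negative correlations are clipped to zero before powering), the
#' configuration this pipeline targets.
#'
#' @param beta Soft-threshold power (>= 1, default 3).
#' @param min_module_size Smallest accepted module (default 30).
#' @param cut_height Static dendrogram cut height in (0, 1] (default 0.99).
#' @param merge_cut Eigengene dissimilarity (1 - correlation) below which
#'   modules are merged (default 0.15); 0 disables merging.
#' @param split_gap Minimum join-height gap for the recursive tree cut to
#'   split a core branch into sub-branches (default 0.1).
#' @param core_height Height below which a branch counts as a coherent
#'   module core (default 0.9). Average-linkage trees on TOM dissimilarity
#'   accrete unassigned genes one by one just below the static cut, so
#'   module cores are recognised as the maximal branches that complete
#'   below this height; genes joining only above it stay unassigned.
#' @return A validated `network_params` list.
#' @export
network_params <- function(beta = 3, min_module_size = 30, cut_height = 0.99,
                           merge_cut = 0.15, split_gap = 0.1,
                           core_height = 0.9) {
  if (beta < 1) abort("`beta` must be >= 1.")
  if (cut_height <= 0 || cut_height > 1) abort("`cut_height` must be in (0, 1].")
  if (merge_cut < 0 || merge_cut >= 1) abort("`merge_cut` must be in [0, 1).")
  if (min_module_size < 1) abort("`min_module_size` must be >= 1.")
  if (split_gap < 0) abort("`split_gap` must be >= 0.")
  if (core_height <= 0 || core_height > cut_height) {
    abort("`core_height` must be in (0, cut_height].")
  }
  structure(
    list(beta = beta, min_module_size = min_module_size,
         cut_height = cut_height, merge_cut = merge_cut,
         split_gap = split_gap, core_height = core_height,
         unassigned_label = "grey"),
    class = "network_params"
  )
}

#' Signed-hybrid adjacency matrix
#'
#' `A_ij = max(bicor(x_i, x_j), 0)^beta` for `i != j`; the diagonal is set
#' to zero for connectivity computations. Genes whose biweight
#' midcorrelation is undefined (all-constant rows) get zero adjacency.
#'
#' @param m An [expr_matrix()] on the `"scaled"` scale with >= 4 samples.
#' @param params A [network_params()] object.
#' @return Symmetric gene x gene adjacency matrix with zero diagonal.
#' @export
adjacency_signed_hybrid <- function(m, params = network_params()) {
  assert_expr_scale(m, "scaled", "adjacency_signed_hybrid()")
  if (ncol(m) < 4) abort("adjacency needs >= 4 samples.")
  r <- bicor_matrix(unclass(m))
  if (all(is.na(r))) abort("all genes are constant; no network to build.")
  r[is.na(r)] <- 0
  a <- pmax(r, 0)^params$beta
  diag(a) <- 0
  dimnames(a) <- list(rownames(m), rownames(m))
  (a + t(a)) / 2
}

#' Topological overlap matrix
#'
#' `omega_ij = (l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' `l_ij = sum_u A_iu A_uj` and connectivity `k_i = sum_u A_iu`;
#' `omega_ii = 1`. The clustering dissimilarity is `1 - omega`.
#'
#' @param a Symmetric adjacency with zero diagonal and entries in `[0, 1]`.
#' @return The TOM similarity matrix.
#' @seealso [tom_dissimilarity()]
#' @export
topological_overlap <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) abort("adjacency must be square.")
  if (max(abs(a - t(a))) > 1e-10) abort("adjacency must be symmetric.")
  if (any(diag(a) != 0)) abort("adjacency diagonal must be zero.")
  if (any(a < 0 | a > 1)) abort("adjacency entries must lie in [0, 1].")
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  omega <- (l + a) / denom
  diag(omega) <- 1
  dimnames(omega) <- dimnames(a)
  (omega + t(omega)) / 2
}

#' @rdname topological_overlap
#' @export
tom_dissimilarity <- function(a) {
  1 - topological_overlap(a)
}

#' Module detection by average-linkage clustering and dynamic tree cut
#'
#' Genes are clustered by average-linkage hierarchical clustering of the TOM
#' dissimilarity and modules are read off the tree in three deterministic
#' steps: (1) sever the dendrogram at `cut_height`; (2) inside each branch,
#' descend past the region where single genes accrete one by one (joins
#' above `core_height`) down to the maximal sub-branches that complete
#' below `core_height` — the module cores; (3) recursively split a core at
#' distinct branch points, i.e. whenever its two sub-branches each hold at
#' least `min_module_size` genes and the join height exceeds the
#' sub-branches' own top heights by at least `split_gap`. Genes outside any
#' core, and cores smaller than `min_module_size`, are left unassigned
#' (`"grey"`). Labels are size-ranked color names.
#'
#' @param dissim Square symmetric dissimilarity matrix (typically
#'   [tom_dissimilarity()]) with gene ids as dimnames.
#' @param params A [network_params()] object.
#' @return Tibble: gene_id, module.
#' @export
detect_modules <- function(dissim, params = network_params()) {
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim)) {
    abort("`dissim` must be square.")
  }
  if (max(abs(dissim - t(dissim))) > 1e-8) abort("`dissim` must be symmetric.")
  n <- nrow(dissim)
  if (params$min_module_size > n) {
    abort("`min_module_size` exceeds the number of genes.")
  }
  gene_ids <- rownames(dissim) %||% paste0("gene", seq_len(n))
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  clusters <- cutree_dynamic_tree(hc, params$cut_height,
                                  params$min_module_size, params$split_gap,
                                  params$core_height)
  module <- label_modules(clusters, params)
  tibble(gene_id = gene_ids, module = module)
}

# tree-variant dynamic cut on an hclust object; returns integer cluster ids
# (0 = unassigned)
cutree_dynamic_tree <- function(hc, cut_height, min_size, split_gap,
                                core_height = cut_height) {
  n <- length(hc$order)
  merge <- hc$merge
  height <- hc$height
  n_nodes <- nrow(merge)

  members <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    left <- merge[i, 1]
    right <- merge[i, 2]
    members[[i]] <- c(
      if (left < 0) -left else members[[left]],
      if (right < 0) -right else members[[right]]
    )
  }
  node_height <- function(x) if (x < 0) 0 else height[x]
  node_size <- function(x) if (x < 0) 1L else length(members[[x]])

  # recursive split below the static roots
  clusters <- integer(n)
  next_id <- 0L
  assign_cluster <- function(node) {
    next_id <<- next_id + 1L
    leaves <- if (node < 0) -node else members[[node]]
    clusters[leaves] <<- next_id
  }
  node_leaves <- function(x) if (x < 0) -x else members[[x]]
  # iterative post-order splitter: accretion chains can be as deep as the
  # gene count, so explicit tasks replace recursion. An asymmetric join
  # (one branch below min_size) descends into the dominant branch and then
  # attaches the straggler leaves to whichever cluster dominates it.
  split_node <- function(node) {
    tasks <- list(list(type = "split", node = node))
    while (length(tasks)) {
      tk <- tasks[[length(tasks)]]
      tasks[[length(tasks)]] <- NULL
      if (tk$type == "attach") {
        big_clusters <- clusters[node_leaves(tk$big)]
        target <- as.integer(names(which.max(table(big_clusters))))
        clusters[node_leaves(tk$small)] <<- target
        next
      }
      nd <- tk$node
      if (nd < 0) {
        assign_cluster(nd)
        next
      }
      left <- merge[nd, 1]
      right <- merge[nd, 2]
      size_l <- node_size(left)
      size_r <- node_size(right)
      gap <- height[nd] - max(node_height(left), node_height(right))
      if (size_l >= min_size && size_r >= min_size && gap >= split_gap) {
        tasks <- c(tasks, list(list(type = "split", node = left),
                               list(type = "split", node = right)))
      } else if (max(size_l, size_r) >= min_size &&
                 min(size_l, size_r) < min_size) {
        big <- if (size_l >= size_r) left else right
        small <- if (size_l >= size_r) right else left
        tasks <- c(tasks, list(list(type = "attach", big = big, small = small),
                               list(type = "split", node = big)))
      } else {
        assign_cluster(nd)
      }
    }
    invisible(NULL)
  }
  # descend past the single-gene accretion region to the module cores
  # (iterative: accretion chains can be as deep as the gene count)
  descend <- function(node) {
    stack <- node
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (cur < 0) next # stray leaf: unassigned
      if (height[cur] <= core_height) {
        split_node(cur)
      } else {
        stack <- c(stack, merge[cur, 1], merge[cur, 2])
      }
    }
    invisible(NULL)
  }

  # static roots: nodes at or below cut_height whose parent merges above it
  parent <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    for (child in merge[i, ]) if (child > 0) parent[child] <- i
  }
  is_root <- height <= cut_height &
    (parent == 0 | height[pmax(parent, 1)] > cut_height)
  for (i in which(is_root)) descend(i)
  # leaves merging only above cut_height stay unassigned (cluster 0)

  sizes <- tabulate(clusters)
  small <- which(sizes < min_size)
  clusters[clusters %in% small] <- 0L
  clusters
}

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue", "violet"
)

# size-ranked color labels; 0 -> grey
label_modules <- function(clusters, params) {
  module <- rep(params$unassigned_label, length(clusters))
  ids <- setdiff(unique(clusters), 0L)
  if (length(ids) == 0) return(module)
  sizes <- vapply(ids, function(i) sum(clusters == i), integer(1))
  ids <- ids[order(-sizes)]
  labels <- c(module_palette, paste0("module", seq_along(ids)))[seq_along(ids)]
  for (j in seq_along(ids)) module[clusters == ids[j]] <- labels[j]
  module
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' module's gene-scaled expression submatrix (unit-norm sample scores),
#' sign-oriented so that its average correlation with the member genes is
#' positive. Size-1 modules return the scaled gene itself (flagged).
#'
#' @param m An [expr_matrix()] covering all labeled genes.
#' @param labels Tibble gene_id/module as returned by [detect_modules()].
#' @param unassigned Label to skip (default `"grey"`).
#' @return A `module_eigengenes` object: `eigengenes` (module x sample
#'   matrix), `var_explained`, `sizes`, `singleton` flags.
#' @export
module_eigengenes <- function(m, labels, unassigned = "grey") {
  missing <- setdiff(labels$gene_id, rownames(m))
  if (length(missing)) {
    abort(paste0("labels cover genes absent from the matrix: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  mods <- setdiff(unique(labels$module), unassigned)
  if (length(mods) == 0) abort("no assigned modules.")
  x <- unclass(scale_genes(expr_matrix(
    unclass(m)[labels$gene_id, , drop = FALSE], expr_scale(m)
  )))

  eig <- matrix(NA_real_, length(mods), ncol(x),
                dimnames = list(mods, colnames(x)))
  var_explained <- numeric(length(mods))
  sizes <- integer(length(mods))
  singleton <- logical(length(mods))
  for (j in seq_along(mods)) {
    rows <- which(labels$module == mods[j])
    sizes[j] <- length(rows)
    sub <- x[rows, , drop = FALSE]
    if (length(rows) == 1) {
      v <- sub[1, ]
      e <- v / sqrt(sum(v^2))
      var_explained[j] <- 1
      singleton[j] <- TRUE
    } else {
      sv <- svd(sub, nu = 0, nv = 1)
      e <- sv$v[, 1]
      var_explained[j] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (mean(as.vector(sub %*% e)) < 0) e <- -e
    eig[j, ] <- e
  }
  structure(
    list(eigengenes = eig, var_explained = setNames(var_explained, mods),
         sizes = setNames(sizes, mods), singleton = setNames(singleton, mods)),
    class = "module_eigengenes"
  )
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - cor(e_i, e_j)` is smallest, while it is below `merge_cut`,
#' recomputing eigengenes after every merge. The smaller module takes the
#' larger module's label.
#'
#' @inheritParams module_eigengenes
#' @param merge_cut Dissimilarity threshold (default 0.15; 0 disables).
#' @return A list: `labels` (tibble gene_id/module), `eigengenes`
#'   ([module_eigengenes()] of the merged labels), `n_merges`.
#' @export
merge_close_modules <- function(m, labels, merge_cut = 0.15,
                                unassigned = "grey") {
  n_merges <- 0L
  repeat {
    me <- module_eigengenes(m, labels, unassigned)
    mods <- rownames(me$eigengenes)
    if (length(mods) < 2 || merge_cut <= 0) break
    d <- 1 - cor(t(me$eigengenes))
    diag(d) <- Inf
    min_d <- min(d)
    if (min_d >= merge_cut) break
    pair <- which(d == min_d, arr.ind = TRUE)[1, ]
    a <- mods[pair[1]]
    b <- mods[pair[2]]
    keep <- if (me$sizes[a] >= me$sizes[b]) a else b
    drop <- setdiff(c(a, b), keep)
    labels$module[labels$module == drop] <- keep
    n_merges <- n_merges + 1L
  }
  list(labels = labels, eigengenes = me, n_merges = n_merges)
}

#' Module-trait correlations
#'
#' Biweight midcorrelation of every module eigengene with every trait,
#' with BH-FDR control across the whole table. Because eigengenes of
#' condition-driven modules are strongly bimodal, the outlier cap of
#' [bicor()] defaults to 0.05 here so the biweight cannot discard a whole
#' condition as outliers.
#'
#' @param eigengenes A [module_eigengenes()] object.
#' @param traits Data frame of per-sample traits (numeric indicators or
#'   hours), rows aligned to the eigengene samples (by `sample_id` column if
#'   present, else by position).
#' @param max_p_outliers Outlier-proportion cap passed to [bicor_with_p()].
#' @return Tibble: module, trait, r, p, q.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     max_p_outliers = 0.05) {
  eig <- eigengenes$eigengenes
  if ("sample_id" %in% names(traits)) {
    if (!setequal(traits$sample_id, colnames(eig))) {
      abort("traits are not aligned to the eigengene samples.")
    }
    traits <- traits[match(colnames(eig), traits$sample_id), , drop = FALSE]
    traits$sample_id <- NULL
  }
  if (nrow(traits) != ncol(eig)) {
    abort("traits must have one row per sample.")
  }
  traits <- traits[vapply(traits, is.numeric, logical(1))]
  if (ncol(traits) == 0) abort("no numeric trait columns.")

  out <- tidyr::expand_grid(module = rownames(eig), trait = names(traits))
  stats <- purrr::map2(out$module, out$trait, function(mo, tr) {
    bicor_with_p(eig[mo, ], traits[[tr]], max_p_outliers)
  })
  out$r <- purrr::map_dbl(stats, "r")
  out$p <- purrr::map_dbl(stats, "p")
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}

#' Full signed-hybrid co-expression analysis
#'
#' Chains [adjacency_signed_hybrid()], [tom_dissimilarity()],
#' [detect_modules()], [merge_close_modules()] and (optionally)
#' [module_trait_correlation()] into a single fitted object.
#'
#' @param m An [expr_matrix()]; scaled internally if needed.
#' @param params A [network_params()] object.
#' @param traits Optional per-sample trait data frame (see
#'   [module_trait_correlation()]).
#' @return A `module_set` object: `labels`, `eigengenes`, `trait_cor`
#'   (or NULL), `params`, `n_merges`.
#' @export
build_coexpression_modules <- function(m, params = network_params(),
                                       traits = NULL) {
  if (expr_scale(m) != "scaled") m <- scale_genes(m)
  a <- adjacency_signed_hybrid(m, params)
  d <- 1 - topological_overlap(a)
  labels <- detect_modules(d, params)
  has_modules <- any(labels$module != params$unassigned_label)
  if (has_modules) {
    merged <- merge_close_modules(m, labels, params$merge_cut,
                                  params$unassigned_label)
    labels <- merged$labels
    eigengenes <- merged$eigengenes
    trait_cor <- if (!is.null(traits)) {
      module_trait_correlation(eigengenes, traits)
    }
  } else {
    eigengenes <- NULL
    trait_cor <- NULL
    merged <- list(n_merges = 0L)
  }
  structure(
    list(labels = labels, eigengenes = eigengenes, trait_cor = trait_cor,
         params = params, n_merges = merged$n_merges),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  tab <- sort(table(x$labels$module), decreasing = TRUE)
  cat("<module_set> ", sum(names(tab) != x$params$unassigned_label),
      " modules over ", nrow(x$labels), " genes\n", sep = "")
  print(tab)
  invisible(x)
}

#' @describeIn build_coexpression_modules Gene-level labels as a tibble.
#' @param x A `module_set`.
#' @param ... Unused.
#' @export
tidy.module_set <- function(x, ...) {
  x$labels
}

#' @describeIn build_coexpression_modules One row per module: size, variance
#'   explained by the eigengene.
#' @export
glance.module_set <- function(x, ...) {
  if (is.null(x$eigengenes)) {
    return(tibble(module = character(), size = integer(),
                  var_explained = numeric()))
  }
  tibble(
    module = names(x$eigengenes$sizes),
    size = unname(x$eigengenes$sizes),
    var_explained = unname(x$eigengenes$var_explained)
  )
}

#' @describeIn build_coexpression_modules Module-trait correlation heatmap
#'   (requires `traits` at fit time).
#' @param object A `module_set`.
#' @export
autoplot.module_set <- function(object, ...) {
  if (is.null(object$trait_cor)) {
    abort("fit with `traits` to plot module-trait correlations.")
  }
  df <- object$trait_cor
  df$label <- sprintf("%.2f\n(%.1e)", df$r, df$q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "bicor") +
    ggplot2::theme_minimal()
}
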
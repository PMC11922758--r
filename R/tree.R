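#' Multi-level cluster hierarchy
#'
#' A `cluster_tree` stores a strictly nested multi-level clustering as a
#' cells x levels label matrix plus a node table (id, level, parent,
#' size) and optional node centroids in an embedding. Child cell sets
#' partition their parent's cell set at every level; the constructor
#' validates this and errors otherwise.
#'
#' @param labels character matrix, cells x levels (coarse to fine),
#'   rownames = cell ids, colnames = level names (e.g. `C1`, `C2`).
#' @param embedding optional cells x dims matrix aligned by rownames;
#'   node centroids are mean member coordinates.
#' @return an object of class `cluster_tree` with elements `cell_ids`,
#'   `levels`, `labels`, `nodes` (data.frame `node_id`, `level`,
#'   `parent`, `n_cells`) and `centroids` (or NULL).
#' @export
cluster_tree <- function(labels, embedding = NULL) {
  labels <- as.matrix(labels)
  if (is.null(rownames(labels)) || is.null(colnames(labels)))
    abort_validation("`labels` needs cell ids as rownames and level names as colnames")
  if (anyNA(labels) || any(labels == ""))
    abort_validation("every cell must be labeled at every level")
  n_levels <- ncol(labels)
  # nestedness: each fine cluster maps into exactly one coarse cluster
  for (l in seq_len(n_levels - 1L)) {
    n_parents <- tapply(labels[, l], labels[, l + 1L],
                        function(x) length(unique(x)))
    if (any(n_parents > 1L))
      abort_validation(
        "labels are not nested: cluster(s) %s at level %s span multiple parents",
        paste(names(n_parents)[n_parents > 1L], collapse = ", "),
        colnames(labels)[l + 1L])
  }
  nodes <- do.call(rbind, lapply(seq_len(n_levels), function(l) {
    ids <- sort(unique(labels[, l]))
    parent <- if (l == 1L) rep(NA_character_, length(ids)) else {
      vapply(ids, function(id)
        labels[match(id, labels[, l]), l - 1L], character(1))
    }
    data.frame(node_id = ids, level = colnames(labels)[l], parent = parent,
               n_cells = as.integer(table(labels[, l])[ids]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  tree <- structure(list(
    cell_ids = rownames(labels),
    levels = colnames(labels),
    labels = labels,
    nodes = nodes,
    centroids = NULL,
    reconciliation_cost = 0L
  ), class = "cluster_tree")
  if (!is.null(embedding)) {
    if (!all(rownames(labels) %in% rownames(embedding)))
      abort_validation("`embedding` does not cover all labeled cells")
    tree$centroids <- compute_node_centroids(tree,
      embedding[rownames(labels), , drop = FALSE])
  }
  tree
}

compute_node_centroids <- function(tree, embedding) {
  cents <- do.call(rbind, lapply(seq_along(tree$levels), function(l) {
    lab <- tree$labels[, l]
    m <- rowsum(embedding, lab)
    m / as.vector(table(lab)[rownames(m)])
  }))
  cents[tree$nodes$node_id, , drop = FALSE]
}

#' @rdname cluster_tree
#' @param x a `cluster_tree`.
#' @param ... ignored.
#' @method print cluster_tree
#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d cells, %d levels (%s)\n",
              length(x$cell_ids), length(x$levels),
              paste(x$levels, collapse = " > ")))
  sizes <- table(x$nodes$level)[x$levels]
  cat(sprintf("  clusters per level: %s\n",
              paste(sprintf("%s=%d", x$levels, sizes), collapse = ", ")))
  invisible(x)
}

#' Cells belonging to a tree node
#' @param tree a [cluster_tree].
#' @param node node id.
#' @param level optional level name (inferred from the node id otherwise).
#' @export
tree_node_cells <- function(tree, node, level = NULL) {
  level <- level %||% tree$nodes$level[match(node, tree$nodes$node_id)]
  if (is.na(level)) abort_validation("unknown node '%s'", node)
  tree$cell_ids[tree$labels[, level] == node]
}

#' Sibling nodes (same parent, same level) of a tree node
#' @inheritParams tree_node_cells
#' @export
tree_siblings <- function(tree, node, level = NULL) {
  i <- match(node, tree$nodes$node_id)
  if (is.na(i)) abort_validation("unknown node '%s'", node)
  lv <- level %||% tree$nodes$level[i]
  p <- tree$nodes$parent[i]
  same <- tree$nodes$level == lv & tree$nodes$node_id != node
  if (is.na(p)) tree$nodes$node_id[same & is.na(tree$nodes$parent)]
  else tree$nodes$node_id[same & !is.na(tree$nodes$parent) &
                            tree$nodes$parent == p]
}

#' Child nodes of a tree node
#' @inheritParams tree_node_cells
#' @export
tree_children <- function(tree, node) {
  tree$nodes$node_id[!is.na(tree$nodes$parent) & tree$nodes$parent == node]
}

#' Reconcile flat consensus clusterings into a nested tree
#'
#' Takes one flat labeling per resolution, ordered coarse to fine, and
#' makes them strictly nested: each fine cluster is attached to the
#' coarse cluster holding the plurality of its cells (ties broken by
#' lexicographically smallest coarse label), after which every cell's
#' coarser labels are overwritten along its majority path. Sweeps repeat
#' until a fixed point (at most `max_iter`); the number of relabeled
#' cell-level entries is reported as the reconciliation cost.
#'
#' @param consensus_per_resolution list of flat labelings (each a vector
#'   over the same cells, named by cell id or aligned to
#'   `rownames(embedding)`), ordered coarse to fine. Names of the list
#'   become level names; unnamed lists get `C1..CK`.
#' @param embedding cells x dims matrix (for node centroids).
#' @param cells optional cell table (unused by the reconciliation, kept
#'   for interface symmetry).
#' @param max_iter sweep bound.
#' @return a [cluster_tree]; `$reconciliation_cost` counts relabelings.
#' @export
build_tree <- function(consensus_per_resolution, embedding, cells = NULL,
                       max_iter = 50L) {
  K <- length(consensus_per_resolution)
  if (K < 1L) abort_validation("need at least one labeling")
  cell_ids <- rownames(embedding)
  if (is.null(cell_ids)) abort_validation("`embedding` needs cell id rownames")
  level_names <- names(consensus_per_resolution) %||% sprintf("C%d", seq_len(K))
  if (is.null(names(consensus_per_resolution)) ||
      any(names(consensus_per_resolution) == ""))
    level_names <- sprintf("C%d", seq_len(K))
  L <- vapply(consensus_per_resolution, function(v) {
    v <- align_to_cells(v, cell_ids, "labeling")
    if (anyNA(v)) abort_validation("labelings must be complete partitions")
    as.character(v)
  }, character(length(cell_ids)))
  colnames(L) <- level_names
  rownames(L) <- cell_ids

  cost <- 0L
  for (iter in seq_len(max_iter)) {
    changed <- 0L
    if (K > 1L) for (l in rev(seq_len(K - 1L))) {
      fine <- L[, l + 1L]
      coarse <- L[, l]
      # plurality parent per fine cluster, ties to smallest coarse label
      tab <- table(fine, coarse)
      parent <- colnames(tab)[apply(tab, 1L, which.max)]
      names(parent) <- rownames(tab)
      new_coarse <- unname(parent[fine])
      changed <- changed + sum(new_coarse != coarse)
      L[, l] <- new_coarse
    }
    cost <- cost + changed
    if (changed == 0L) break
  }
  if (changed > 0L)
    warning("tree reconciliation did not reach a fixed point within ",
            max_iter, " sweeps; reconciliation cost so far: ", cost)

  for (l in seq_len(K))
    L[, l] <- paste0(level_names[l], "-", L[, l])
  tree <- cluster_tree(L, embedding = embedding)
  tree$reconciliation_cost <- cost
  tree
}

#' Pruning configuration for consensus trees
#'
#' A node is merged into its nearest sibling (Euclidean centroid
#' distance in the embedding) when it has fewer than
#' `min_strong_markers` strong sibling-markers, fewer than `min_cells`
#' cells, or more than `max_single_donor_fraction` of its cells from one
#' donor. A "strong" marker is a gene with Bonferroni-adjusted p below
#' `strong_marker_alpha` and log2 fold change of at least
#' `strong_marker_min_lfc` versus the node's siblings. Pruning repeats
#' `n_iterations` times or until no node fails.
#'
#' @param min_strong_markers,min_cells,max_single_donor_fraction,n_iterations
#'   the three merge criteria and the repeat count.
#' @param strong_marker_alpha,strong_marker_min_lfc what counts as a
#'   strong marker.
#' @export
prune_config <- function(min_strong_markers = 5L, min_cells = 50L,
                         max_single_donor_fraction = 0.90,
                         n_iterations = 5L, strong_marker_alpha = 0.05,
                         strong_marker_min_lfc = 0.5) {
  structure(list(
    min_strong_markers = check_count(min_strong_markers,
                                     "min_strong_markers", lower = 0L),
    min_cells = check_count(min_cells, "min_cells", lower = 1L),
    max_single_donor_fraction = check_scalar_number(
      max_single_donor_fraction, "max_single_donor_fraction",
      lower = 0, upper = 1, strict_lower = TRUE),
    n_iterations = check_count(n_iterations, "n_iterations"),
    strong_marker_alpha = check_scalar_number(strong_marker_alpha,
                                              "strong_marker_alpha",
                                              lower = 0, upper = 1,
                                              strict_lower = TRUE),
    strong_marker_min_lfc = check_scalar_number(strong_marker_min_lfc,
                                                "strong_marker_min_lfc",
                                                lower = 0)
  ), class = "prune_config")
}

#' Merge under-supported tree nodes into their nearest siblings
#'
#' Per iteration, every node with at least one sibling is checked
#' against the three criteria in [prune_config()]; failing nodes are
#' merged into the sibling with the smallest Euclidean centroid
#' distance, smallest nodes first (ties by node id). Centroids are kept
#' current as merges are applied; markers and criteria are re-evaluated
#' at the start of each iteration. Nodes without siblings are left in
#' place.
#'
#' @param tree a [cluster_tree] with centroids.
#' @param counts genes x cells matrix for the marker criterion, or NULL
#'   to skip it.
#' @param cells cell table providing `donor_id` and `batch_id` (aligned
#'   by `cell_id`).
#' @param cfg a [prune_config()].
#' @param embedding cells x dims matrix used to recompute centroids
#'   (required).
#' @return the pruned [cluster_tree], with attributes `prune_log`
#'   (data.frame of merges), `iterations_used` and `converged` (whether
#'   no node failed before the iteration budget ran out).
#' @export
prune_tree <- function(tree, counts, cells, cfg = prune_config(),
                       embedding = NULL) {
  if (is.null(embedding)) abort_validation("`embedding` is required")
  check_columns(cells, c("cell_id", "donor_id", "batch_id"), "cells")
  if (!all(tree$cell_ids %in% cells$cell_id))
    abort_validation("`cells` does not cover all tree cells")
  donor <- stats::setNames(cells$donor_id, cells$cell_id)[tree$cell_ids]
  batch <- stats::setNames(cells$batch_id, cells$cell_id)[tree$cell_ids]
  emb <- embedding[tree$cell_ids, , drop = FALSE]

  log_rows <- list()
  converged <- FALSE
  iterations_used <- 0L
  for (iter in seq_len(cfg$n_iterations)) {
    iterations_used <- iter
    status <- evaluate_prune_criteria(tree, counts, donor, batch, cfg)
    failing <- status[status$fails & status$has_sibling, , drop = FALSE]
    if (!nrow(failing)) { converged <- TRUE; break }
    failing <- failing[order(failing$n_cells, failing$node_id), ,
                       drop = FALSE]
    for (i in seq_len(nrow(failing))) {
      node <- failing$node_id[i]
      lv <- failing$level[i]
      if (!(node %in% tree$nodes$node_id)) next  # absorbed earlier
      sibs <- tree_siblings(tree, node, lv)
      if (!length(sibs)) next
      dists <- vapply(sibs, function(s)
        euclidean_dist(tree$centroids[node, ], tree$centroids[s, ]),
        numeric(1))
      ord <- order(dists, sibs)
      target <- sibs[ord[1L]]
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        iteration = iter, node = node, level = lv,
        n_cells = failing$n_cells[i], reason = failing$reason[i],
        target = target, distance = dists[ord[1L]],
        stringsAsFactors = FALSE)
      tree <- merge_tree_node(tree, node, target, lv, emb)
    }
  }
  if (!converged && iterations_used == cfg$n_iterations) {
    status <- evaluate_prune_criteria(tree, counts, donor, batch, cfg)
    converged <- !any(status$fails & status$has_sibling)
  }
  attr(tree, "prune_log") <- if (length(log_rows))
    do.call(rbind, log_rows) else
    data.frame(iteration = integer(), node = character(),
               level = character(), n_cells = integer(),
               reason = character(), target = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  attr(tree, "iterations_used") <- iterations_used
  attr(tree, "converged") <- converged
  tree
}

evaluate_prune_criteria <- function(tree, counts, donor, batch, cfg) {
  nodes <- tree$nodes
  res <- lapply(seq_len(nrow(nodes)), function(i) {
    node <- nodes$node_id[i]
    lv <- nodes$level[i]
    sibs <- tree_siblings(tree, node, lv)
    if (!length(sibs))
      return(data.frame(node_id = node, level = lv,
                        n_cells = nodes$n_cells[i], has_sibling = FALSE,
                        fails = FALSE, reason = "", stringsAsFactors = FALSE))
    reasons <- character(0)
    if (nodes$n_cells[i] < cfg$min_cells) reasons <- c(reasons, "min_cells")
    members <- tree_node_cells(tree, node, lv)
    dfrac <- max(table(donor[members])) / length(members)
    if (dfrac > cfg$max_single_donor_fraction)
      reasons <- c(reasons, "donor_fraction")
    if (!is.null(counts)) {
      mk <- find_markers(counts, tree$labels[, lv], batch, node,
                         background = "siblings", tree = tree, level = lv)
      n_strong <- sum(mk$p_adj < cfg$strong_marker_alpha &
                        mk$lfc >= cfg$strong_marker_min_lfc)
      if (n_strong < cfg$min_strong_markers)
        reasons <- c(reasons, "strong_markers")
    }
    data.frame(node_id = node, level = lv, n_cells = nodes$n_cells[i],
               has_sibling = TRUE, fails = length(reasons) > 0,
               reason = paste(reasons, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

merge_tree_node <- function(tree, node, target, level, embedding) {
  labels <- tree$labels
  labels[labels[, level] == node, level] <- target
  out <- cluster_tree(labels, embedding = embedding)
  out$reconciliation_cost <- tree$reconciliation_cost
  out
}

#' Select clusters by percentile of a gene's expression fraction
#'
#' Computes, per cluster, the fraction of cells with nonzero counts for
#' the gene, then returns the clusters at or above the requested
#' percentile (linear interpolation) of that per-cluster fraction
#' distribution — the rule used to shortlist clusters for genes of
#' interest (99th percentile for highly restricted neuropeptides, 95th
#' for receptors).
#'
#' @param counts genes x cells matrix.
#' @param labels cluster label per cell.
#' @param gene gene id (must be a rowname of `counts`).
#' @param percentile percentile in \[0, 100).
#' @return character vector of cluster ids.
#' @export
select_clusters_by_expression <- function(counts, labels, gene, percentile) {
  check_scalar_number(percentile, "percentile", lower = 0, upper = 100,
                      strict_upper = TRUE)
  if (!(gene %in% rownames(counts)))
    abort_validation("gene '%s' not present in counts", gene)
  labels <- align_to_cells(labels, colnames(counts), "labels")
  expressed <- as.vector(counts[gene, ] > 0)
  frac <- tapply(expressed, labels, mean)
  if (max(frac) == 0) return(character(0))  # gene silent everywhere
  cutoff <- stats::quantile(frac, percentile / 100, names = FALSE)
  names(frac)[frac >= cutoff]
}
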
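#' Signature-gene filter configuration for deconvolution references
#'
#' Genes enter the reference signature when expressed in at least
#' `min_cell_fraction` of cells, or are rescued when expressed in at
#' least `rescue_min_fraction` of cells with a mean of their nonzero
#' counts strictly above `rescue_min_nonzero_mean` (low-detection,
#' high-magnitude genes).
#'
#' @param min_cell_fraction main detection gate (default 8% of cells).
#' @param rescue_min_fraction rescue floor (default 0.05% of cells).
#' @param rescue_min_nonzero_mean rescue nonzero-mean gate (strict).
#' @export
signature_filter_config <- function(min_cell_fraction = 0.08,
                                    rescue_min_fraction = 0.0005,
                                    rescue_min_nonzero_mean = 1.4) {
  structure(list(
    min_cell_fraction = check_scalar_number(min_cell_fraction,
                                            "min_cell_fraction", 0, 1,
                                            strict_lower = TRUE,
                                            strict_upper = TRUE),
    rescue_min_fraction = check_scalar_number(rescue_min_fraction,
                                              "rescue_min_fraction", 0, 1,
                                              strict_lower = TRUE,
                                              strict_upper = TRUE),
    rescue_min_nonzero_mean = check_scalar_number(rescue_min_nonzero_mean,
                                                  "rescue_min_nonzero_mean",
                                                  lower = 0)
  ), class = "signature_filter_config")
}

#' Filter genes for deconvolution reference signatures
#'
#' @param counts genes x cells matrix.
#' @param cfg a [signature_filter_config()].
#' @return character vector of kept gene ids.
#' @export
filter_signature_genes <- function(counts, cfg = signature_filter_config()) {
  nz <- Matrix::rowSums(counts > 0)
  frac <- nz / ncol(counts)
  total <- Matrix::rowSums(counts)
  nzmean <- ifelse(nz > 0, total / nz, 0)
  keep <- frac >= cfg$min_cell_fraction |
    (frac >= cfg$rescue_min_fraction & nzmean > cfg$rescue_min_nonzero_mean)
  genes <- rownames(counts)[keep]
  if (!length(genes))
    abort_validation("no gene passes the signature filter")
  genes
}

#' Define spatial regions by clustering spots on abundance profiles
#'
#' kNN graph on the spots' cluster-abundance vectors (per-cluster
#' z-scored by default, so abundant ubiquitous clusters do not dominate
#' the metric) followed by Leiden clustering.
#'
#' @param abundance spots x clusters nonnegative matrix.
#' @param k_neighbors kNN degree (must be < number of spots).
#' @param resolution Leiden resolution.
#' @param seed RNG seed.
#' @param standardize z-score each cluster's abundances across spots
#'   before computing distances (raw scale if `FALSE`).
#' @return named character vector spot -> region id (`R1`, `R2`, ...).
#' @export
cluster_spots <- function(abundance, k_neighbors = 15L, resolution = 1,
                          seed = 1L, standardize = TRUE) {
  abundance <- as.matrix(abundance)
  if (nrow(abundance) < 2L) abort_validation("need at least 2 spots")
  if (k_neighbors >= nrow(abundance))
    abort_validation("k_neighbors (%d) must be < n_spots (%d)",
                     k_neighbors, nrow(abundance))
  if (any(abundance < 0)) abort_validation("abundances must be nonnegative")
  spot_ids <- rownames(abundance) %||% as.character(seq_len(nrow(abundance)))
  # identical profiles carry no structure: one region, by definition
  if (nrow(unique(abundance)) == 1L)
    return(stats::setNames(rep("R1", nrow(abundance)), spot_ids))
  x <- if (standardize) {
    apply(abundance, 2L, function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    })
  } else abundance
  rownames(x) <- rownames(abundance)
  g <- knn_graph(x, k_neighbors)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 5L)))
  stats::setNames(sprintf("R%d", as.integer(memb)), spot_ids)
}

#' Merge spot regions according to a curation map
#'
#' Relabels regions by the user-supplied map (e.g. grouping several
#' Leiden spot clusters that belong to the same anatomical region);
#' unmapped regions pass through unchanged.
#'
#' @param labels named spot -> region vector.
#' @param merge_map named character vector, region -> group name.
#' @export
merge_regions <- function(labels, merge_map) {
  if (!length(merge_map)) return(labels)
  hit <- labels %in% names(merge_map)
  labels[hit] <- merge_map[labels[hit]]
  labels
}

#' Score cluster-region assignments by MAD-normalized adjusted abundance
#'
#' For cluster `c` and region `r`: `mean` is the mean spot abundance of
#' `c` over the spots of `r`; `adj` subtracts, per cluster, the median
#' across regions of these regional means (centring away ubiquitous
#' clusters); `mad` is the unscaled median absolute deviation of the
#' spot-level abundances within the region (floored at
#' `1e-6 x` the global mean abundance to avoid division by zero); and
#' `mad_x = adj / mad` is the assignment score.
#'
#' @param abundance spots x clusters matrix.
#' @param regions named spot -> region vector covering every spot.
#' @return data.frame of class `assignment_table` with one row per
#'   cluster x region: `cluster`, `region`, `mean`, `adj`, `mad`,
#'   `mad_x`, `mad_floored`.
#' @export
score_region_assignment <- function(abundance, regions) {
  abundance <- as.matrix(abundance)
  spots <- rownames(abundance)
  if (is.null(spots) || !all(spots %in% names(regions)))
    abort_validation("`regions` must label every spot of `abundance`")
  regions <- regions[spots]
  region_ids <- sort(unique(unname(regions)))
  small <- names(which(table(regions) < 3L))
  if (length(small))
    warning("region(s) with fewer than 3 spots (MAD unreliable): ",
            paste(small, collapse = ", "))
  clusters <- colnames(abundance) %||% sprintf("K%d", seq_len(ncol(abundance)))
  colnames(abundance) <- clusters
  eps <- 1e-6 * mean(abundance)

  means <- rowsum(abundance, unname(regions)) /
    as.vector(table(regions)[region_ids])
  means <- means[region_ids, , drop = FALSE]           # regions x clusters
  med_of_means <- apply(means, 2L, stats::median)
  adj <- sweep(means, 2L, med_of_means, "-")
  mads <- sapply(clusters, function(cl) {
    vapply(region_ids, function(r) {
      v <- abundance[regions == r, cl]
      stats::median(abs(v - stats::median(v)))
    }, numeric(1))
  })
  mads <- matrix(mads, nrow = length(region_ids),
                 dimnames = list(region_ids, clusters))
  out <- data.frame(
    cluster = rep(clusters, each = length(region_ids)),
    region = rep(region_ids, times = length(clusters)),
    mean = as.vector(means),
    adj = as.vector(adj),
    mad = as.vector(mads),
    mad_x = as.vector(adj) / pmax(as.vector(mads), eps),
    mad_floored = as.vector(mads) < eps,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assignment_table", class(out))
  attr(out, "mad_floor") <- eps
  out
}

#' Assign clusters to regions from an assignment table
#'
#' Per cluster the candidate region is the one with the highest adjusted
#' mean abundance; it is assigned iff its `mad_x` strictly exceeds the
#' threshold, otherwise the cluster stays unassigned (`NA`, low
#' confidence). Manual curation overrides, if given, are applied last
#' and recorded in the `overrides` attribute — never silently.
#'
#' @param table an [score_region_assignment()] result.
#' @param threshold `mad_x` gate (strict; default 10).
#' @param overrides optional named vector cluster -> region (or NA).
#' @return named character vector cluster -> region or NA, with
#'   attribute `overrides` listing applied overrides.
#' @export
assign_clusters <- function(table, threshold = 10, overrides = NULL) {
  clusters <- unique(table$cluster)
  out <- vapply(clusters, function(cl) {
    rows <- table[table$cluster == cl, , drop = FALSE]
    rows <- rows[order(-rows$adj, rows$region), , drop = FALSE]
    if (rows$mad_x[1L] > threshold) rows$region[1L] else NA_character_
  }, character(1))
  applied <- character(0)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), clusters)
    if (length(bad))
      abort_validation("override(s) for unknown cluster(s): %s",
                       paste(bad, collapse = ", "))
    out[names(overrides)] <- overrides
    applied <- names(overrides)
  }
  attr(out, "overrides") <- applied
  out
}

#' Propagate region assignments from a parent level to a child level
#'
#' Each child cluster inherits its parent's region (or NA) — the rule
#' used to carry robust parent-level assignments down to fine clusters.
#'
#' @param tree a [cluster_tree].
#' @param parent_assignments named vector parent node -> region/NA.
#' @param parent_level,child_level level names in `tree`.
#' @return named vector child node -> region/NA.
#' @export
propagate_assignments <- function(tree, parent_assignments, parent_level,
                                  child_level) {
  kids <- tree$nodes[tree$nodes$level == child_level, , drop = FALSE]
  if (!nrow(kids)) return(stats::setNames(character(0), character(0)))
  if (!all(kids$parent %in% names(parent_assignments)))
    abort_validation("parent assignment missing for some %s nodes",
                     child_level)
  stats::setNames(unname(parent_assignments[kids$parent]), kids$node_id)
}
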
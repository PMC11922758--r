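#' Cross-species matching configuration
#'
#' @param adjusted_threshold edges require adjusted correlation strictly
#'   greater than this.
#' @param hvg_per_species highly variable genes taken per species before
#'   intersecting.
#' @export
match_config <- function(adjusted_threshold = 0.7, hvg_per_species = 2500L) {
  structure(list(
    adjusted_threshold = check_scalar_number(adjusted_threshold,
                                             "adjusted_threshold",
                                             lower = -1, upper = 1,
                                             strict_lower = TRUE,
                                             strict_upper = TRUE),
    hvg_per_species = check_count(hvg_per_species, "hvg_per_species")
  ), class = "match_config")
}

#' Reduce a homology table to a one-to-one gene map
#'
#' Whenever a gene participates in several homolog pairs, only its
#' highest-similarity pair is retained; the result is injective in both
#' directions. Ties are broken towards the lexicographically smaller
#' partner gene id.
#'
#' @param table data.frame with columns `gene_a`, `gene_b`,
#'   `similarity`.
#' @return the retained rows (a partial 1:1 map).
#' @export
reduce_homologs <- function(table) {
  check_columns(table, c("gene_a", "gene_b", "similarity"), "homology table")
  if (!nrow(table)) abort_validation("homology table is empty")
  if (any(!is.finite(table$similarity)))
    abort_validation("similarity must be finite")
  key <- paste(table$gene_a, table$gene_b, sep = "\r")
  if (anyDuplicated(key))
    abort_validation("duplicate homolog pair(s): %s",
                     paste(unique(sub("\r", " / ", key[duplicated(key)])),
                           collapse = ", "))
  ord <- order(-table$similarity, table$gene_a, table$gene_b)
  tab <- table[ord, , drop = FALSE]
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$gene_a[i] %in% used_a || tab$gene_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, tab$gene_a[i])
    used_b <- c(used_b, tab$gene_b[i])
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared highly variable genes across two species
#'
#' Per species, genes are ranked by the number of samples/batches in
#' which they are flagged highly variable (descending), with ties broken
#' by mean per-sample variance rank (ascending; requires `var_a`/
#' `var_b`) and then gene id; the top `hvg_per_species` per species are
#' intersected.
#'
#' @param flags_a,flags_b logical gene x sample matrices of per-sample
#'   HVG flags (rownames = homolog-mapped gene ids).
#' @param cfg a [match_config()].
#' @param var_a,var_b optional numeric gene x sample matrices of
#'   per-sample expression variances used for the tie break.
#' @return character vector of shared genes.
#' @export
select_shared_hvgs <- function(flags_a, flags_b, cfg = match_config(),
                               var_a = NULL, var_b = NULL) {
  top_genes <- function(flags, vars, n) {
    occ <- rowSums(flags)
    tie <- if (!is.null(vars)) {
      rowMeans(apply(-vars, 2L, rank))
    } else rep(0, nrow(flags))
    ord <- order(-occ, tie, rownames(flags))
    ord <- ord[occ[ord] > 0]   # a gene flagged nowhere is not an HVG
    rownames(flags)[ord][seq_len(min(n, length(ord)))]
  }
  a <- top_genes(as.matrix(flags_a), var_a, cfg$hvg_per_species)
  b <- top_genes(as.matrix(flags_b), var_b, cfg$hvg_per_species)
  shared <- intersect(a, b)
  if (!length(shared))
    abort_validation(paste("no shared HVGs; lower hvg stringency or check",
                           "that flags use homolog-mapped gene ids"))
  shared
}

#' Pearson correlation between cluster centroids of two species
#'
#' Centroid of a cluster = mean embedding vector of its cells; entry
#' (i, j) is the Pearson correlation between centroid i of species A and
#' centroid j of species B across embedding dimensions.
#'
#' @param joint_embedding cells x dims matrix covering both species.
#' @param labels_a,labels_b named cluster labels (cell id -> cluster).
#' @return matrix (A clusters x B clusters) of correlations.
#' @export
correlate_centroids <- function(joint_embedding, labels_a, labels_b) {
  if (ncol(joint_embedding) < 3L)
    abort_validation("embedding dimension must be >= 3 for centroid correlation")
  cent <- function(labels) {
    cells <- names(labels)
    if (is.null(cells) || !all(cells %in% rownames(joint_embedding)))
      abort_validation("labels must be named by cell ids present in the embedding")
    m <- rowsum(joint_embedding[cells, , drop = FALSE], unname(labels))
    m / as.vector(table(unname(labels))[rownames(m)])
  }
  ca <- cent(labels_a)
  cb <- cent(labels_b)
  stats::cor(t(ca), t(cb))
}

#' Adjust a correlation matrix towards its row/column maxima
#'
#' For entry `r` with row maximum `M_i` and column maximum `M_j`, the
#' one-sided adjustments subtract the gap to the maximum from the value
#' itself (`2r - M`); entries that are their own row and column maxima
#' are unchanged. `mode = "min"` (default) takes the minimum of the two
#' one-sided adjustments, making a downstream threshold symmetric in
#' both species; `"row"`/`"col"` return a single orientation.
#'
#' @param corr correlation matrix (A x B).
#' @param mode `"min"`, `"row"` or `"col"`.
#' @export
adjust_correlations <- function(corr, mode = c("min", "row", "col")) {
  mode <- match.arg(mode)
  if (any(!is.finite(corr))) abort_validation("correlations must be finite")
  row_max <- apply(corr, 1L, max)
  col_max <- apply(corr, 2L, max)
  adj_row <- 2 * corr - row_max
  adj_col <- sweep(2 * corr, 2L, col_max, "-")
  switch(mode,
         min = pmin(adj_row, adj_col),
         row = adj_row,
         col = adj_col)
}

#' Build the cross-species match graph
#'
#' Bipartite graph on the clusters of the two species with an edge
#' wherever the adjusted correlation strictly exceeds the threshold;
#' raw correlations are stored alongside.
#'
#' @param adjusted adjusted correlation matrix (A x B) from
#'   [adjust_correlations()].
#' @param cfg a [match_config()].
#' @param raw optional raw correlation matrix with the same dimnames.
#' @return an object of class `match_graph`: list with `edges`
#'   (data.frame `a`, `b`, `r`, `adj`, `type`), `nodes_a`, `nodes_b`.
#' @export
build_match_graph <- function(adjusted, cfg = match_config(), raw = NULL) {
  nodes_a <- rownames(adjusted) %||% sprintf("A-%d", seq_len(nrow(adjusted)))
  nodes_b <- colnames(adjusted) %||% sprintf("B-%d", seq_len(ncol(adjusted)))
  idx <- which(adjusted > cfg$adjusted_threshold, arr.ind = TRUE)
  edges <- data.frame(
    a = nodes_a[idx[, 1L]],
    b = nodes_b[idx[, 2L]],
    r = if (!is.null(raw)) raw[idx] else rep(NA_real_, nrow(idx)),
    adj = adjusted[idx],
    type = rep(NA_character_, nrow(idx)),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes_a = nodes_a, nodes_b = nodes_b),
            class = "match_graph")
}

#' Prune a match graph to stars (remove M:N relationships)
#'
#' Implements the rule: 1:N edges are kept when the neighbouring
#' clusters have no other edges; if a node's neighbours themselves have
#' several edges, only that node's maximum-adjusted-correlation edge is
#' retained. Nodes are processed in lexical (species, id) order and the
#' rule is iterated to a fixed point (a single pass is available via
#' `single_pass`), after which every connected component is a star —
#' at most one node of degree above 1. Relationship types are then
#' assigned: lone edges are `1:1`, a star centred on a species-A node is
#' `1:N`, on a species-B node `M:1`. Equal adjusted weights are broken
#' towards the lexicographically smaller partner.
#'
#' @param graph a `match_graph`.
#' @param single_pass stop after one sweep instead of iterating.
#' @return the pruned `match_graph` with `type` filled in.
#' @export
prune_match_graph <- function(graph, single_pass = FALSE) {
  edges <- graph$edges
  node_order <- c(paste0("A\r", sort(graph$nodes_a)),
                  paste0("B\r", sort(graph$nodes_b)))
  repeat {
    changed <- FALSE
    for (v in node_order) {
      side <- substr(v, 1, 1)
      id <- substring(v, 3)
      own <- if (side == "A") which(edges$a == id) else which(edges$b == id)
      if (length(own) < 2L) next
      partners <- if (side == "A") edges$b[own] else edges$a[own]
      partner_deg <- vapply(partners, function(p) {
        if (side == "A") sum(edges$b == p) else sum(edges$a == p)
      }, integer(1))
      if (!any(partner_deg >= 2L)) next
      ord <- order(-edges$adj[own], partners)
      edges <- edges[-own[ord[-1L]], , drop = FALSE]
      changed <- TRUE
    }
    if (!changed || single_pass) break
  }
  rownames(edges) <- NULL
  deg_a <- table(edges$a)
  deg_b <- table(edges$b)
  edges$type <- vapply(seq_len(nrow(edges)), function(i) {
    da <- deg_a[[edges$a[i]]]
    db <- deg_b[[edges$b[i]]]
    if (da == 1L && db == 1L) "1:1" else if (da > 1L) "1:N" else "M:1"
  }, character(1))
  graph$edges <- edges
  graph
}

#' Per-cluster summary of a pruned match graph
#'
#' One row per cluster of both species: matched partners ordered by
#' descending raw correlation, the relationship type, and an unmatched
#' flag for clusters with no surviving edge.
#'
#' @param graph a pruned `match_graph`.
#' @param all_clusters_a,all_clusters_b the complete cluster sets
#'   (clusters absent from the graph are reported unmatched).
#' @return data.frame with `cluster`, `species`, `partners`
#'   (comma-separated, best first), `type`, `unmatched`.
#' @export
match_summary <- function(graph, all_clusters_a = graph$nodes_a,
                          all_clusters_b = graph$nodes_b) {
  edges <- graph$edges
  row_for <- function(cl, species) {
    own <- if (species == "A") edges[edges$a == cl, , drop = FALSE]
           else edges[edges$b == cl, , drop = FALSE]
    partners <- if (species == "A") own$b else own$a
    ord <- order(-own$r, partners)
    data.frame(cluster = cl, species = species,
               partners = paste(partners[ord], collapse = ","),
               type = if (nrow(own)) own$type[1L] else NA_character_,
               unmatched = nrow(own) == 0L,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(sort(all_clusters_a), row_for, species = "A")),
    do.call(rbind, lapply(sort(all_clusters_b), row_for, species = "B"))
  )
  rownames(out) <- NULL
  out
}

#' Run the full cross-species matching pipeline
#'
#' Centroid correlation in the joint embedding, correlation adjustment,
#' thresholded graph construction, and star pruning.
#'
#' @inheritParams correlate_centroids
#' @param cfg a [match_config()].
#' @param adjust_mode passed to [adjust_correlations()].
#' @return list with `correlations`, `adjusted`, `graph` (pruned) and
#'   `summary`.
#' @export
match_species_clusters <- function(joint_embedding, labels_a, labels_b,
                                   cfg = match_config(),
                                   adjust_mode = "min") {
  r <- correlate_centroids(joint_embedding, labels_a, labels_b)
  adj <- adjust_correlations(r, mode = adjust_mode)
  graph <- prune_match_graph(build_match_graph(adj, cfg, raw = r))
  list(correlations = r, adjusted = adj, graph = graph,
       summary = match_summary(graph))
}
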
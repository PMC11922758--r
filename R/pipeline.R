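#' Run the full synthetic end-to-end pipeline
#'
#' Generates a planted hierarchy with counts, applies QC, builds and
#' prunes the consensus tree, matches clusters across a simulated
#' species pair, assigns clusters to spatial regions from a simulated
#' abundance map, and selects effector genes from simulated
#' specificity/rank tables. All outputs (tree JSON/Newick, label,
#' match, assignment and effector tables, JSON-lines log) are written
#' under `out_dir`; everything is deterministic given `config$seed`.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir overrides `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL, seed = NULL) {
  config$seed <- seed %||% config$seed
  config$out_dir <- out_dir %||% config$out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.jsonl")
  unlink(logf)
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL   # hash the analysis settings, not the path
  hash <- config_hash(cfg_for_hash)
  log_line <- function(stage, ...) {
    entry <- c(list(stage = stage, seed = config$seed,
                    config_hash = hash,
                    package_version = as.character(
                      utils::packageVersion("hypoatlas"))),
               list(...))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
        file = logf, append = TRUE, sep = "")
  }

  # --- synthetic inputs -------------------------------------------------
  h <- config$hierarchy
  sim <- simulate_hierarchy(hierarchy_spec(
    levels = h$levels, cells_per_leaf = h$cells_per_leaf,
    embedding_dim = h$embedding_dim, separation = h$separation,
    noise_sd = h$noise_sd, n_donors = h$n_donors, n_batches = h$n_batches,
    level_decay = h$level_decay, seed = config$seed))
  cn <- config$counts
  cnt <- simulate_counts(sim$tree, sim$cells, n_genes = cn$n_genes,
                         markers_per_leaf = cn$markers_per_leaf,
                         batch_effect_sd = cn$batch_effect_sd,
                         seed = config$seed + 1L,
                         marker_fold = cn$marker_fold)
  log_line("simulate", n_cells = nrow(sim$cells), n_genes = cn$n_genes)

  # --- QC ---------------------------------------------------------------
  q <- config$qc
  qcfg <- qc_config(q$min_umi, q$max_mito, q$doublet_cluster_fraction)
  leaf_level <- sim$tree$levels[length(sim$tree$levels)]
  cells <- sim$cells
  cells[[leaf_level]] <- sim$tree$labels[cells$cell_id, leaf_level]
  flt <- filter_nuclei(cells, qcfg)
  kept <- drop_doublet_clusters(flt$kept, leaf_level, qcfg)
  emb <- sim$embedding[kept$cell_id, , drop = FALSE]
  counts <- cnt$counts[, kept$cell_id, drop = FALSE]
  write_cell_table(kept, file.path(config$out_dir, "cells_qc.tsv"))
  log_line("qc", n_input = nrow(cells), n_kept = nrow(kept),
           summary = as.list(flt$summary))

  # --- consensus tree ---------------------------------------------------
  tr <- config$tree
  graph <- knn_graph(emb, tr$k_neighbors)
  consensus <- lapply(sort(unlist(tr$resolutions)), function(res) {
    ens <- run_leiden_ensemble(emb, resolution = res, n_runs = tr$n_runs,
                               k_neighbors = tr$k_neighbors,
                               base_seed = config$seed + 10L, graph = graph)
    consensus_partition(ens)
  })
  tree <- build_tree(consensus, emb)
  p <- config$prune
  pcfg <- prune_config(p$min_strong_markers, p$min_cells,
                       p$max_single_donor_fraction, p$n_iterations,
                       p$strong_marker_alpha, p$strong_marker_min_lfc)
  tree <- prune_tree(tree, counts, kept, pcfg, embedding = emb)
  export_tree(tree, file.path(config$out_dir, "tree.json"), "json")
  export_tree(tree, file.path(config$out_dir, "tree.newick"), "newick")
  write_labels(tree$labels, file.path(config$out_dir, "labels.tsv"))
  write_table_tsv(attr(tree, "prune_log"),
                  file.path(config$out_dir, "prune_log.tsv"))
  log_line("tree", n_nodes = nrow(tree$nodes),
           reconciliation_cost = tree$reconciliation_cost,
           prune_merges = nrow(attr(tree, "prune_log")),
           converged = attr(tree, "converged"))

  # --- cross-species matching ------------------------------------------
  s <- config$species
  sp <- simulate_species_pair(species_pair_spec(
    shared_leaves = s$shared_leaves, a_only_leaves = s$a_only_leaves,
    b_only_leaves = s$b_only_leaves, cells_per_leaf = s$cells_per_leaf,
    embedding_dim = s$embedding_dim, divergence_sd = s$divergence_sd,
    noise_sd = s$noise_sd, seed = config$seed + 2L))
  mcfg <- match_config(config$match$adjusted_threshold,
                       config$match$hvg_per_species)
  match <- match_species_clusters(sp$embedding, sp$labels_a, sp$labels_b,
                                  mcfg)
  write_table_tsv(match$summary,
                  file.path(config$out_dir, "match_table.tsv"))
  write_table_tsv(match$graph$edges,
                  file.path(config$out_dir, "match_edges.tsv"))
  log_line("xmatch", n_edges = nrow(match$graph$edges),
           n_unmatched = sum(match$summary$unmatched))

  # --- spatial regions --------------------------------------------------
  sc <- config$spatial
  n_cl <- sc$planted_clusters + sc$flat_clusters
  affinity <- matrix(sc$baseline, nrow = n_cl, ncol = sc$n_regions)
  for (i in seq_len(sc$planted_clusters))
    affinity[i, ((i - 1L) %% sc$n_regions) + 1L] <- sc$peak
  spat <- simulate_spatial(spatial_spec(
    n_regions = sc$n_regions, spots_per_region = sc$spots_per_region,
    n_clusters = n_cl, affinity = affinity, noise_sd = sc$noise_sd,
    seed = config$seed + 3L))
  regions <- cluster_spots(spat$abundance, k_neighbors = sc$k_neighbors,
                           resolution = sc$resolution,
                           seed = config$seed + 4L)
  atab <- score_region_assignment(spat$abundance, regions)
  assignments <- assign_clusters(atab, threshold = sc$mad_x_threshold)
  write_labels(regions, file.path(config$out_dir, "regions.tsv"))
  write_table_tsv(atab, file.path(config$out_dir, "assignment_table.tsv"))
  write_table_tsv(
    data.frame(cluster = names(assignments),
               region = ifelse(is.na(assignments), "NA", assignments),
               stringsAsFactors = FALSE),
    file.path(config$out_dir, "assignments.tsv"))
  log_line("regions", n_regions = length(unique(regions)),
           n_assigned = sum(!is.na(assignments)))

  # --- effector genes ---------------------------------------------------
  e <- config$effectors
  gene_ids <- sprintf("g%05d", seq_len(e$n_genes))
  planted <- with_seed(config$seed + 5L, sample(gene_ids, e$n_planted))
  gw <- simulate_gwas_tables(e$n_genes, e$n_celltypes, planted,
                             seed = config$seed + 6L,
                             specificity_percentile = e$specificity_percentile,
                             top_n = e$top_n_genes)
  ecfg <- effector_config(specificity_percentile = e$specificity_percentile,
                          top_n_genes = e$top_n_genes)
  effectors <- select_effector_genes(gw$specificity, gw$ranks, ecfg)
  write_table_tsv(effectors, file.path(config$out_dir, "effectors.tsv"))
  log_line("effectors", n_planted = e$n_planted,
           n_selected = nrow(effectors))

  invisible(list(tree = tree, match = match, assignments = assignments,
                 effectors = effectors, kept_cells = kept,
                 out_dir = config$out_dir))
}
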
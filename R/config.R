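#' Default pipeline configuration
#'
#' Nested list mirroring the stage configurations (QC, tree building,
#' pruning, cross-species matching, spatial assignment, effector
#' selection) plus the synthetic-data generators that feed the packaged
#' end-to-end demo. Values are desk-scale; the QC, pruning, matching,
#' mad_x and effector thresholds are the reference defaults.
#'
#' @return a named nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "hypoatlas_out",
    hierarchy = list(levels = c(2L, 3L), cells_per_leaf = 120L,
                     embedding_dim = 10L, separation = 8, noise_sd = 1,
                     n_donors = 4L, n_batches = 2L, level_decay = 0.5),
    counts = list(n_genes = 150L, markers_per_leaf = 8L,
                  batch_effect_sd = 0.2, marker_fold = 10),
    qc = list(min_umi = 800L, max_mito = 0.10,
              doublet_cluster_fraction = 0.75),
    tree = list(resolutions = c(0.05, 1), n_runs = 10L, k_neighbors = 15L),
    prune = list(min_strong_markers = 5L, min_cells = 50L,
                 max_single_donor_fraction = 0.90, n_iterations = 5L,
                 strong_marker_alpha = 0.05, strong_marker_min_lfc = 0.5),
    species = list(shared_leaves = 10L, a_only_leaves = 3L,
                   b_only_leaves = 3L, cells_per_leaf = 60L,
                   embedding_dim = 50L, divergence_sd = 1 / 3,
                   noise_sd = 1),
    match = list(adjusted_threshold = 0.7, hvg_per_species = 2500L),
    spatial = list(n_regions = 6L, spots_per_region = 40L,
                   planted_clusters = 12L, flat_clusters = 4L,
                   peak = 10, baseline = 1, noise_sd = 0.2,
                   k_neighbors = 15L, resolution = 1,
                   mad_x_threshold = 10),
    effectors = list(n_genes = 2000L, n_celltypes = 12L, n_planted = 40L,
                     specificity_percentile = 95, top_n_genes = 200L)
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' Unknown keys are rejected (no silent typo absorption); omitted keys
#' fall back to [default_pipeline_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path))
           jsonlite::read_json(path, simplifyVector = TRUE)
         else abort_validation("config must be .yaml/.yml or .json: %s", path)
  defaults <- default_pipeline_config()
  merged <- merge_config(defaults, raw, path = "")
  structure(merged, class = "pipeline_config")
}

merge_config <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort_validation("unknown config key(s)%s: %s",
                     if (nzchar(path)) paste0(" under '", path, "'") else "",
                     paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], user[[k]],
                   paste0(path, if (nzchar(path)) "." else "", k))
    else user[[k]]
  }
  defaults
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @param path output file (`.yaml` or `.json`).
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(unclass(config), path, precision = 15L)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
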
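#' Nucleus-level quality-control configuration
#'
#' Defaults follow the global thresholds used for human hypothalamus
#' snRNA-seq: a minimum of 800 UMIs per nucleus, at most 10%
#' mitochondrial RNA, and removal of clusters in which more than 75% of
#' members are flagged doublets. Bounds are inclusive for the nucleus
#' filters ("minimum"/"maximum") and strict for the doublet-cluster rule
#' ("more than").
#'
#' @param min_umi minimum UMI count kept (inclusive).
#' @param max_mito maximum mitochondrial fraction kept (inclusive).
#' @param doublet_cluster_fraction clusters whose doublet fraction
#'   strictly exceeds this are dropped entirely.
#' @export
qc_config <- function(min_umi = 800L, max_mito = 0.10,
                      doublet_cluster_fraction = 0.75) {
  structure(list(
    min_umi = check_count(min_umi, "min_umi", lower = 0L),
    max_mito = check_scalar_number(max_mito, "max_mito", lower = 0, upper = 1,
                                   strict_lower = TRUE),
    doublet_cluster_fraction = check_scalar_number(
      doublet_cluster_fraction, "doublet_cluster_fraction",
      lower = 0, upper = 1, strict_lower = TRUE)
  ), class = "qc_config")
}

qc_required_fields <- c("cell_id", "umi_count", "mito_fraction",
                        "doublet_flag")

#' Filter nuclei on UMI count, mitochondrial fraction and doublet flag
#'
#' A nucleus is kept iff `umi_count >= min_umi`,
#' `mito_fraction <= max_mito` and `doublet_flag` is `FALSE`. Kept and
#' removed tables partition the input.
#'
#' @param cells cell table with columns `cell_id`, `umi_count`,
#'   `mito_fraction`, `doublet_flag` (plus anything else, preserved).
#' @param cfg a [qc_config()].
#' @param sample_overrides optional data.frame (`sample_id`, `min_umi`,
#'   `max_mito`) of per-sample thresholds overriding the global defaults.
#' @return list with `kept`, `removed` (data.frames) and `summary`
#'   (named counts, including per-criterion removal counts).
#' @export
filter_nuclei <- function(cells, cfg = qc_config(), sample_overrides = NULL) {
  check_columns(cells, qc_required_fields, "cell table")
  if (anyDuplicated(cells$cell_id))
    abort_validation("cell_id values must be unique")
  min_umi <- rep(cfg$min_umi, nrow(cells))
  max_mito <- rep(cfg$max_mito, nrow(cells))
  if (!is.null(sample_overrides)) {
    check_columns(cells, "sample_id", "cell table (for sample_overrides)")
    check_columns(sample_overrides, c("sample_id", "min_umi", "max_mito"),
                  "sample_overrides")
    m <- match(cells$sample_id, sample_overrides$sample_id)
    hit <- !is.na(m)
    min_umi[hit] <- sample_overrides$min_umi[m[hit]]
    max_mito[hit] <- sample_overrides$max_mito[m[hit]]
  }
  low_umi <- cells$umi_count < min_umi
  high_mito <- cells$mito_fraction > max_mito
  doublet <- as.logical(cells$doublet_flag)
  keep <- !low_umi & !high_mito & !doublet
  list(
    kept = cells[keep, , drop = FALSE],
    removed = cells[!keep, , drop = FALSE],
    summary = c(n_input = nrow(cells), n_kept = sum(keep),
                n_removed = sum(!keep), n_low_umi = sum(low_umi),
                n_high_mito = sum(high_mito), n_doublet = sum(doublet))
  )
}

#' Remove whole clusters dominated by doublets
#'
#' Clusters (at the given label column) whose fraction of
#' doublet-flagged members strictly exceeds
#' `cfg$doublet_cluster_fraction` are removed in full, doublet and
#' singlet members alike. Applied after the nucleus-level filters.
#'
#' @param cells cell table with `doublet_flag` and a label column.
#' @param level name of the cluster label column.
#' @param cfg a [qc_config()].
#' @return the filtered cell table.
#' @export
drop_doublet_clusters <- function(cells, level, cfg = qc_config()) {
  check_columns(cells, c("doublet_flag", level), "cell table")
  lab <- cells[[level]]
  if (anyNA(lab) || any(lab == ""))
    abort_validation("all cells must be labeled at level '%s'", level)
  frac <- tapply(as.logical(cells$doublet_flag), lab, mean)
  bad <- names(frac)[frac > cfg$doublet_cluster_fraction]
  cells[!(lab %in% bad), , drop = FALSE]
}
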
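#' Effector-gene selection configuration
#'
#' @param specificity_percentile per-cell-type percentile cutoff over
#'   nonzero specificity values (default 95).
#' @param top_n_genes association-rank gate (default top 1,000).
#' @param n_subsets,subset_size bootstrap design for
#'   [bootstrap_specificity()] (default ten subsets of 100,000 cells).
#' @param celltype_alpha,n_celltypes_tested Bonferroni threshold pieces
#'   for [prioritize_celltypes()].
#' @export
effector_config <- function(specificity_percentile = 95,
                            top_n_genes = 1000L, n_subsets = 10L,
                            subset_size = 100000L, celltype_alpha = 0.05,
                            n_celltypes_tested = NULL) {
  structure(list(
    specificity_percentile = check_scalar_number(specificity_percentile,
                                                 "specificity_percentile",
                                                 lower = 0, upper = 100,
                                                 strict_lower = TRUE,
                                                 strict_upper = TRUE),
    top_n_genes = check_count(top_n_genes, "top_n_genes"),
    n_subsets = check_count(n_subsets, "n_subsets"),
    subset_size = check_count(subset_size, "subset_size"),
    celltype_alpha = check_scalar_number(celltype_alpha, "celltype_alpha",
                                         lower = 0, upper = 1,
                                         strict_lower = TRUE),
    n_celltypes_tested = if (!is.null(n_celltypes_tested))
      check_count(n_celltypes_tested, "n_celltypes_tested") else NULL
  ), class = "effector_config")
}

#' Built-in expression-specificity score
#'
#' Normalized mean expression: for each gene, the cell-type mean divided
#' by the sum of cell-type means (zero for genes silent everywhere).
#' Values lie in \[0, 1\] and sum to 1 across cell types per expressed
#' gene. A deliberately simple default for the pluggable specificity
#' slot of [bootstrap_specificity()]; any gene x cell-type scorer with
#' values in \[0, 1\] (e.g. an ESmu-style score) can be substituted.
#'
#' @param counts genes x cells matrix.
#' @param labels cell-type label per cell.
#' @return genes x cell types matrix in \[0, 1\].
#' @export
specificity_mean_norm <- function(counts, labels) {
  labels <- align_to_cells(labels, colnames(counts), "labels")
  f <- factor(labels)
  x <- as_dense_matrix(counts)
  means <- sapply(levels(f), function(l)
    rowMeans(x[, f == l, drop = FALSE]))
  tot <- rowSums(means)
  out <- means / ifelse(tot > 0, tot, 1)
  out[tot == 0, ] <- 0
  out
}

#' Bootstrap-aggregated cell-type specificity
#'
#' Draws `n_subsets` random cell subsets (without replacement within a
#' subset; subsets independent across replicates, or disjoint with
#' `disjoint = TRUE`), applies the pluggable specificity function to
#' each, and returns the elementwise mean over the full gene x cell-type
#' universe. Genes or cell types absent from a subset contribute zero to
#' the mean, with a warning.
#'
#' @param counts genes x cells matrix.
#' @param labels cell-type label per cell.
#' @param spec_fn function `(counts, labels) -> matrix` with values in
#'   \[0, 1\]; default [specificity_mean_norm()].
#' @param cfg an [effector_config()].
#' @param seed RNG seed.
#' @param disjoint partition the cells instead of drawing subsets
#'   independently.
#' @return genes x cell types specificity matrix.
#' @export
bootstrap_specificity <- function(counts, labels,
                                  spec_fn = specificity_mean_norm,
                                  cfg = effector_config(), seed = 1L,
                                  disjoint = FALSE) {
  n_cells <- ncol(counts)
  if (cfg$subset_size > n_cells)
    abort_validation("subset_size (%d) exceeds n_cells (%d)",
                     cfg$subset_size, n_cells)
  labels <- align_to_cells(labels, colnames(counts), "labels")
  all_genes <- rownames(counts)
  all_types <- sort(unique(labels))
  acc <- matrix(0, length(all_genes), length(all_types),
                dimnames = list(all_genes, all_types))
  missing_any <- FALSE
  with_seed(seed, {
    pool <- if (disjoint) sample(n_cells) else NULL
    for (s in seq_len(cfg$n_subsets)) {
      idx <- if (disjoint) {
        lo <- (s - 1L) * cfg$subset_size
        if (lo + cfg$subset_size > n_cells)
          abort_validation("disjoint subsets need n_subsets*subset_size <= n_cells")
        pool[(lo + 1L):(lo + cfg$subset_size)]
      } else sample(n_cells, cfg$subset_size)
      m <- spec_fn(counts[, idx, drop = FALSE], labels[idx])
      if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
        abort_validation("spec_fn returned values outside [0, 1]")
      if (!all(all_types %in% colnames(m)) ||
          !all(all_genes %in% rownames(m))) missing_any <- TRUE
      gi <- intersect(rownames(m), all_genes)
      ci <- intersect(colnames(m), all_types)
      acc[gi, ci] <- acc[gi, ci] + m[gi, ci, drop = FALSE]
    }
  })
  if (missing_any)
    warning("some genes/cell types were absent from a bootstrap subset ",
            "and contribute 0 to the mean")
  acc / cfg$n_subsets
}

#' Bonferroni prioritization of cell types
#'
#' A cell type is significant iff its p value is strictly below
#' `celltype_alpha / n_celltypes_tested` (e.g. 0.05/452 when 452 cell
#' types are tested).
#'
#' @param celltype_pvalues named numeric vector, cell type -> p.
#' @param cfg an [effector_config()]; `n_celltypes_tested` defaults to
#'   the number of p values supplied.
#' @return character vector of significant cell types.
#' @export
prioritize_celltypes <- function(celltype_pvalues, cfg = effector_config()) {
  if (!length(celltype_pvalues)) return(character(0))
  n <- cfg$n_celltypes_tested %||% length(celltype_pvalues)
  names(celltype_pvalues)[celltype_pvalues < cfg$celltype_alpha / n]
}

#' Select effector genes by specificity percentile and association rank
#'
#' Per cell type, the specificity cutoff is the configured percentile
#' (linear interpolation) of that cell type's nonzero specificity
#' values; a gene is selected iff it strictly exceeds the cutoff in at
#' least one cell type AND its association rank is within the top
#' `top_n_genes`. Supporting cell types are recorded.
#'
#' @param spec genes x cell types specificity matrix.
#' @param ranks data.frame with columns `gene` and `rank` (1 =
#'   strongest association).
#' @param cfg an [effector_config()].
#' @param scope `"per_celltype"` (default) computes the percentile per
#'   cell type; `"global"` pools all nonzero specificity values.
#' @return data.frame `gene`, `celltypes` (comma-separated supporters),
#'   `best_celltype`, `best_specificity`, `rank`, ordered by rank.
#' @export
select_effector_genes <- function(spec, ranks, cfg = effector_config(),
                                  scope = c("per_celltype", "global")) {
  scope <- match.arg(scope)
  check_columns(ranks, c("gene", "rank"), "rank table")
  genes <- intersect(rownames(spec), ranks$gene)
  if (!length(genes))
    abort_validation("specificity matrix and rank table share no genes")
  spec <- spec[genes, , drop = FALSE]
  rank_of <- stats::setNames(ranks$rank, ranks$gene)[genes]
  cutoffs <- if (scope == "per_celltype") {
    apply(spec, 2L, function(v) {
      nz <- v[v > 0]
      if (!length(nz)) return(Inf)
      stats::quantile(nz, cfg$specificity_percentile / 100, names = FALSE)
    })
  } else {
    nz <- spec[spec > 0]
    rep(if (length(nz))
      stats::quantile(nz, cfg$specificity_percentile / 100, names = FALSE)
      else Inf, ncol(spec))
  }
  passes <- sweep(spec, 2L, cutoffs, ">")
  hit <- rowSums(passes) >= 1 & rank_of <= cfg$top_n_genes
  sel <- which(hit)
  out <- data.frame(
    gene = genes[sel],
    celltypes = vapply(sel, function(i)
      paste(colnames(spec)[passes[i, ]], collapse = ","), character(1)),
    best_celltype = vapply(sel, function(i) {
      cand <- which(passes[i, ])
      colnames(spec)[cand[which.max(spec[i, cand])]]
    }, character(1)),
    best_specificity = vapply(sel, function(i)
      max(spec[i, passes[i, ]]), numeric(1)),
    rank = unname(rank_of[sel]),
    stringsAsFactors = FALSE
  )
  out[order(out$rank), , drop = FALSE]
}

#' Bonferroni prioritization of effector genes from burden tests
#'
#' A gene is significant iff its burden-test p value is strictly below
#' `alpha / n_genes_tested` (e.g. 0.05/426 over 426 effector genes).
#'
#' @param gene_pvalues named numeric vector, gene -> p.
#' @param n_genes_tested number of tests in the correction.
#' @param alpha family-wise error rate.
#' @return character vector of significant genes.
#' @export
prioritize_effector_burden <- function(gene_pvalues, n_genes_tested,
                                       alpha = 0.05) {
  n_genes_tested <- check_count(n_genes_tested, "n_genes_tested")
  if (!length(gene_pvalues)) return(character(0))
  names(gene_pvalues)[gene_pvalues < alpha / n_genes_tested]
}
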
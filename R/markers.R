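#' Batch-stratified Wilcoxon rank-sum test for one gene
#'
#' Van Elteren-style combination: within every stratum the Wilcoxon
#' rank-sum statistic of the target group is centred and the per-stratum
#' contributions are combined with weights `1 / (n1 + n2 + 1)` (giving
#' each stratum the locally most powerful weight `n1 * n2 / (n + 1)` on
#' the U scale), standardized with the tie-corrected variance, and
#' referred to a two-sided normal.
#'
#' @param values numeric vector (one gene across cells).
#' @param is_target logical vector, `TRUE` for target-group cells.
#' @param stratum stratum (batch) id per cell.
#' @return list with `z`, `p`, and the per-stratum pieces.
#' @export
stratified_wilcoxon <- function(values, is_target, stratum) {
  stopifnot(length(values) == length(is_target),
            length(values) == length(stratum))
  num <- 0; den <- 0; used <- 0L
  for (s in unique(stratum)) {
    sel <- stratum == s
    g <- is_target[sel]
    n1 <- sum(g); n2 <- sum(!g); n <- n1 + n2
    if (n1 == 0L || n2 == 0L) next
    used <- used + 1L
    r <- rank(values[sel])
    W <- sum(r[g])
    E <- n1 * (n + 1) / 2
    tt <- table(values[sel])
    tie <- sum(tt^3 - tt)
    V <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    num <- num + (W - E) / (n + 1)
    den <- den + V / (n + 1)^2
  }
  if (used == 0L) abort_validation("no comparable stratum")
  z <- if (den > 0) num / sqrt(den) else 0
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n_strata = used)
}

#' Marker genes of a cluster by batch-stratified rank-sum test
#'
#' Tests every gene for differential expression between a target cluster
#' and a background (all other cells, or the cluster's siblings in a
#' tree), stratifying by batch so that multiplicative batch effects
#' cancel within strata. P values are Bonferroni-corrected over the
#' genes tested. Strata lacking cells on either side are dropped; if no
#' stratum remains the test errors.
#'
#' @param counts genes x cells matrix (sparse or dense), colnames = cell
#'   ids.
#' @param labels cluster label per cell (named by cell id, or aligned to
#'   `colnames(counts)`).
#' @param batch batch id per cell (same alignment).
#' @param target cluster id to test.
#' @param background `"all_other"` or `"siblings"` (requires `tree` and
#'   `level`).
#' @param tree,level a [cluster_tree] and level name locating `target`'s
#'   siblings when `background = "siblings"`.
#' @return data.frame with one row per gene: `gene`, `cluster`,
#'   `comparison`, `z`, `p`, `p_adj`, `lfc` (log2 fold change of means,
#'   pseudocount 1) and `detect_diff` (detection-rate difference).
#' @export
find_markers <- function(counts, labels, batch, target,
                         background = c("all_other", "siblings"),
                         tree = NULL, level = NULL) {
  background <- match.arg(background)
  cells <- colnames(counts)
  if (is.null(cells)) abort_validation("`counts` must have cell ids as colnames")
  labels <- align_to_cells(labels, cells, "labels")
  batch <- align_to_cells(batch, cells, "batch")
  t_cells <- cells[!is.na(labels) & labels == target]
  if (!length(t_cells)) abort_validation("target cluster '%s' is empty", target)
  b_cells <- if (background == "all_other") {
    cells[!is.na(labels) & labels != target]
  } else {
    if (is.null(tree) || is.null(level))
      abort_validation("background='siblings' requires `tree` and `level`")
    sibs <- tree_siblings(tree, target, level)
    unlist(lapply(sibs, function(s) tree_node_cells(tree, s, level)),
           use.names = FALSE)
  }
  b_cells <- intersect(b_cells, cells)
  if (!length(b_cells)) abort_validation("background for '%s' is empty", target)

  all_cells <- c(t_cells, b_cells)
  is_t <- c(rep(TRUE, length(t_cells)), rep(FALSE, length(b_cells)))
  strat <- batch[match(all_cells, cells)]
  x <- as_dense_matrix(counts[, all_cells, drop = FALSE])

  num <- numeric(nrow(x)); den <- numeric(nrow(x)); used <- 0L
  for (s in unique(strat)) {
    sel <- strat == s
    g <- is_t[sel]
    n1 <- sum(g); n2 <- sum(!g); n <- n1 + n2
    if (n1 == 0L || n2 == 0L) next
    used <- used + 1L
    xs <- x[, sel, drop = FALSE]
    stats_s <- apply(xs, 1L, function(v) {
      r <- rank(v)
      tt <- table(v)
      c(sum(r[g]), sum(tt^3 - tt))
    })
    W <- stats_s[1L, ]
    tie <- stats_s[2L, ]
    E <- n1 * (n + 1) / 2
    V <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    num <- num + (W - E) / (n + 1)
    den <- den + V / (n + 1)^2
  }
  if (used == 0L) abort_validation("no comparable stratum")
  z <- ifelse(den > 0, num / sqrt(pmax(den, .Machine$double.eps)), 0)
  p <- 2 * stats::pnorm(-abs(z))
  mean_t <- rowMeans(x[, is_t, drop = FALSE])
  mean_b <- rowMeans(x[, !is_t, drop = FALSE])
  data.frame(
    gene = rownames(x) %||% sprintf("g%d", seq_len(nrow(x))),
    cluster = target,
    comparison = if (background == "all_other") "vs_all" else "vs_sibling",
    z = z,
    p = p,
    p_adj = pmin(1, p * nrow(x)),
    lfc = log2((mean_t + 1) / (mean_b + 1)),
    detect_diff = rowMeans(x[, is_t, drop = FALSE] > 0) -
      rowMeans(x[, !is_t, drop = FALSE] > 0),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

align_to_cells <- function(v, cells, what) {
  if (!is.null(names(v))) {
    if (!all(cells %in% names(v)))
      abort_validation("`%s` does not cover all cells in `counts`", what)
    return(unname(v[cells]))
  }
  if (length(v) != length(cells))
    abort_validation("`%s` must be named by cell id or match ncol(counts)",
                     what)
  v
}
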
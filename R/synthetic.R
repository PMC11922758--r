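#' Specification of a planted cluster hierarchy
#'
#' Describes a nested set of Gaussian blobs in a latent embedding space:
#' `levels` gives the branching factor at each level of the hierarchy
#' (so `c(3, 4)` means 3 coarse classes each split into 4 leaves),
#' `separation` the expected Euclidean distance between sibling centroids
#' at the top level, and `level_decay` the factor by which that spacing
#' shrinks per level. Cells are drawn around leaf centroids with isotropic
#' noise of standard deviation `noise_sd` and assigned to donors and
#' batches at random.
#'
#' @param levels integer vector of branching factors, coarse to fine.
#' @param cells_per_leaf cells drawn per leaf cluster.
#' @param embedding_dim dimensionality of the latent space.
#' @param separation sibling centroid distance at the top level
#'   (embedding units). Children are placed at the vertices of a
#'   randomly rotated regular simplex around their parent, so sibling
#'   distances equal the planted value exactly. `0` plants no structure
#'   at all.
#' @param noise_sd within-cluster standard deviation per dimension.
#' @param n_donors,n_batches number of donors and processing batches.
#' @param level_decay multiplicative decay of sibling spacing per level;
#'   values below 1 make coarse classes farther apart than their leaves,
#'   which is what lets graph clustering see both scales (see the
#'   methods vignette for the feasibility band this default sits in).
#' @param donor_imbalance nonnegative; 0 assigns donors uniformly, larger
#'   values skew cell counts towards later donors.
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @return an object of class `hierarchy_spec`.
#' @export
hierarchy_spec <- function(levels, cells_per_leaf = 200L, embedding_dim = 10L,
                           separation = 8, noise_sd = 1, n_donors = 4L,
                           n_batches = 2L, level_decay = 0.7,
                           donor_imbalance = 0, seed = 1L) {
  if (length(levels) < 1L) abort_validation("`levels` must be non-empty")
  levels <- vapply(seq_along(levels), function(i)
    check_count(levels[i], sprintf("levels[%d]", i)), integer(1))
  if (max(levels) > embedding_dim + 1L)
    abort_validation(
      "branching factor %d needs embedding_dim >= %d (simplex placement)",
      max(levels), max(levels) - 1L)
  spec <- list(
    levels = levels,
    cells_per_leaf = check_count(cells_per_leaf, "cells_per_leaf"),
    embedding_dim = check_count(embedding_dim, "embedding_dim"),
    separation = check_scalar_number(separation, "separation", lower = 0),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", lower = 0,
                                   strict_lower = TRUE),
    n_donors = check_count(n_donors, "n_donors"),
    n_batches = check_count(n_batches, "n_batches"),
    level_decay = check_scalar_number(level_decay, "level_decay", lower = 0,
                                      strict_lower = TRUE),
    donor_imbalance = check_scalar_number(donor_imbalance, "donor_imbalance",
                                          lower = 0),
    seed = check_count(seed, "seed", lower = -.Machine$integer.max)
  )
  structure(spec, class = "hierarchy_spec")
}

#' Simulate a latent embedding with a planted cluster hierarchy
#'
#' Places nested cluster centroids: the children of each node sit at
#' the vertices of a regular simplex (side = that level's planted
#' separation) under an independent random rotation, centred on the
#' parent centroid, so sibling centroid distances equal the planted
#' value exactly at every level. Cells are then drawn around the leaf
#' centroids with isotropic Gaussian noise. The returned truth tree
#' records every cell's full path.
#'
#' @param spec a [hierarchy_spec()].
#' @return a list with elements `embedding` (cells x dims matrix),
#'   `cells` (a cell table with donor, batch, UMI, mito and doublet
#'   columns), and `tree` (the true [cluster_tree] whose centroids are
#'   the planted, not the empirical, centroids).
#' @export
simulate_hierarchy <- function(spec) {
  if (!inherits(spec, "hierarchy_spec"))
    abort_validation("`spec` must be a hierarchy_spec")
  with_seed(spec$seed, {
    d <- spec$embedding_dim
    n_levels <- length(spec$levels)
    # centroids per level: list of matrices (clusters x d), lexicographic
    # path order so cluster j at level l has parent ceiling(j / levels[l])
    centroids <- vector("list", n_levels)
    parent_mat <- matrix(0, nrow = 1, ncol = d)
    for (l in seq_len(n_levels)) {
      s_l <- spec$separation * spec$level_decay^(l - 1)
      b <- spec$levels[l]
      kids <- do.call(rbind, lapply(seq_len(nrow(parent_mat)), function(i)
        simplex_vertices(b, s_l, d, parent_mat[i, ])))
      centroids[[l]] <- kids
      parent_mat <- kids
    }
    n_leaves <- prod(spec$levels)
    n_cells <- n_leaves * spec$cells_per_leaf
    leaf_of_cell <- rep(seq_len(n_leaves), each = spec$cells_per_leaf)
    emb <- centroids[[n_levels]][leaf_of_cell, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * d, sd = spec$noise_sd), ncol = d)
    cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
    rownames(emb) <- cell_ids
    colnames(emb) <- sprintf("dim_%02d", seq_len(d))

    # full label path per cell
    level_names <- sprintf("C%d", seq_len(n_levels))
    labels <- matrix("", nrow = n_cells, ncol = n_levels,
                     dimnames = list(cell_ids, level_names))
    idx <- leaf_of_cell
    for (l in rev(seq_len(n_levels))) {
      labels[, l] <- sprintf("%s-%d", level_names[l], idx)
      idx <- ceiling(idx / spec$levels[l])
    }

    donor_p <- exp(spec$donor_imbalance * seq_len(spec$n_donors))
    donor <- sample(sprintf("D%d", seq_len(spec$n_donors)), n_cells,
                    replace = TRUE, prob = donor_p / sum(donor_p))
    batch <- sample(sprintf("B%d", seq_len(spec$n_batches)), n_cells,
                    replace = TRUE)
    cells <- data.frame(
      cell_id = cell_ids,
      umi_count = 1L + stats::rnbinom(n_cells, mu = 3000, size = 8),
      mito_fraction = stats::rbeta(n_cells, 2, 40),
      donor_id = donor,
      sample_id = paste0(donor, ".", batch),
      batch_id = batch,
      doublet_flag = stats::runif(n_cells) < 0.02,
      stringsAsFactors = FALSE
    )

    tree <- cluster_tree(labels, embedding = emb)
    # overwrite empirical centroids with the planted ones (the truth)
    planted <- do.call(rbind, lapply(seq_len(n_levels), function(l) {
      m <- centroids[[l]]
      rownames(m) <- sprintf("%s-%d", level_names[l], seq_len(nrow(m)))
      m
    }))
    tree$centroids <- planted[rownames(tree$centroids), , drop = FALSE]
    list(embedding = emb, cells = cells, tree = tree)
  })
}

# b mutually equidistant points (side s) in d dims, randomly rotated,
# centred on `center`; consumes RNG state (caller seeds).
simplex_vertices <- function(b, s, d, center) {
  v <- (diag(b) - 1 / b) * s / sqrt(2)
  v <- cbind(v, matrix(0, b, d - b))[, seq_len(d), drop = FALSE]
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  sweep(v %*% q, 2L, center, "+")
}

#' Simulate counts with planted marker genes and batch effects
#'
#' Gamma-Poisson (negative binomial) counts on top of log-normal gene
#' baselines. Each leaf of the truth tree receives `markers_per_leaf`
#' dedicated genes whose mean is multiplied by `marker_fold` in that leaf
#' only; every batch multiplies every gene by a log-normal factor shared
#' by all its cells, which is exactly the nuisance a batch-stratified
#' marker test must absorb.
#'
#' @param truth a [cluster_tree] covering all cells to simulate.
#' @param cells cell table aligned with `truth` (provides `batch_id`).
#' @param n_genes total genes.
#' @param markers_per_leaf planted markers per leaf (disjoint across
#'   leaves); 0 plants a pure null.
#' @param batch_effect_sd sd (log scale) of per-batch gene factors.
#' @param seed RNG seed.
#' @param marker_fold fold change of a marker in its own leaf.
#' @param base_mean median baseline mean per gene.
#' @param dispersion negative binomial size parameter.
#' @return list with `counts` (genes x cells sparse dgCMatrix) and
#'   `markers` (data.frame gene, leaf recording the planted truth).
#' @export
simulate_counts <- function(truth, cells, n_genes, markers_per_leaf,
                            batch_effect_sd = 0.2, seed = 1L,
                            marker_fold = 10, base_mean = 0.3,
                            dispersion = 2) {
  n_genes <- check_count(n_genes, "n_genes")
  markers_per_leaf <- check_count(markers_per_leaf, "markers_per_leaf",
                                  lower = 0L)
  check_scalar_number(batch_effect_sd, "batch_effect_sd", lower = 0)
  check_columns(cells, c("cell_id", "batch_id"), "cells")
  if (!identical(cells$cell_id, truth$cell_ids))
    abort_validation("`cells` and `truth` must cover the same cells in order")
  leaf_level <- truth$levels[length(truth$levels)]
  leaf_of_cell <- truth$labels[, leaf_level]
  leaves <- sort(unique(leaf_of_cell))
  if (markers_per_leaf * length(leaves) > n_genes)
    abort_validation("markers_per_leaf * leaves (%d) exceeds n_genes (%d)",
                     markers_per_leaf * length(leaves), n_genes)
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    mu <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 1)
    marker_genes <- if (markers_per_leaf > 0)
      sample(n_genes, markers_per_leaf * length(leaves)) else integer(0)
    markers <- data.frame(
      gene = gene_ids[marker_genes],
      leaf = rep(leaves, each = markers_per_leaf),
      stringsAsFactors = FALSE
    )
    batches <- sort(unique(cells$batch_id))
    bfac <- matrix(stats::rlnorm(n_genes * length(batches),
                                 sdlog = batch_effect_sd),
                   nrow = n_genes,
                   dimnames = list(gene_ids, batches))
    counts <- matrix(0L, nrow = n_genes, ncol = nrow(cells),
                     dimnames = list(gene_ids, cells$cell_id))
    for (b in batches) {
      for (lf in leaves) {
        sel <- which(cells$batch_id == b & leaf_of_cell == lf)
        if (!length(sel)) next
        mu_blk <- mu * bfac[, b]
        own <- markers$gene[markers$leaf == lf]
        mu_blk[match(own, gene_ids)] <- mu_blk[match(own, gene_ids)] *
          marker_fold
        counts[, sel] <- stats::rnbinom(n_genes * length(sel),
                                        mu = rep(mu_blk, length(sel)),
                                        size = dispersion)
      }
    }
    empty <- which(colSums(counts) == 0)
    if (length(empty)) counts[which.max(mu), empty] <- 1L
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         markers = markers)
  })
}

#' Specification of a two-species cluster pair
#'
#' Shared leaves draw both species' centroids from a common ancestral
#' centroid with independent symmetric perturbations of sd
#' `divergence_sd` per side, giving an expected cross-species centroid
#' correlation of `1 / (1 + divergence_sd^2)` (see
#' [divergence_for_correlation()]). Private leaves get independent
#' centroids.
#'
#' @param shared_leaves,a_only_leaves,b_only_leaves cluster counts.
#' @param cells_per_leaf,embedding_dim,noise_sd as in [hierarchy_spec()].
#' @param divergence_sd per-side centroid perturbation sd.
#' @param homolog_fraction fraction of genes with a retained homolog;
#'   recorded in the truth for downstream homology-table emulation.
#' @param seed RNG seed.
#' @export
species_pair_spec <- function(shared_leaves = 20L, a_only_leaves = 5L,
                              b_only_leaves = 5L, cells_per_leaf = 100L,
                              embedding_dim = 50L, divergence_sd = 1 / 3,
                              noise_sd = 1, homolog_fraction = 1,
                              seed = 1L) {
  spec <- list(
    shared_leaves = check_count(shared_leaves, "shared_leaves", lower = 0L),
    a_only_leaves = check_count(a_only_leaves, "a_only_leaves", lower = 0L),
    b_only_leaves = check_count(b_only_leaves, "b_only_leaves", lower = 0L),
    cells_per_leaf = check_count(cells_per_leaf, "cells_per_leaf"),
    embedding_dim = check_count(embedding_dim, "embedding_dim"),
    divergence_sd = check_scalar_number(divergence_sd, "divergence_sd",
                                        lower = 0),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", lower = 0,
                                   strict_lower = TRUE),
    homolog_fraction = check_scalar_number(homolog_fraction,
                                           "homolog_fraction", 0, 1),
    seed = check_count(seed, "seed", lower = -.Machine$integer.max)
  )
  if (spec$shared_leaves + spec$a_only_leaves == 0L ||
      spec$shared_leaves + spec$b_only_leaves == 0L)
    abort_validation("each species needs at least one cluster")
  structure(spec, class = "species_pair_spec")
}

#' Divergence sd that yields a target cross-species centroid correlation
#'
#' Under the symmetric perturbation model of [species_pair_spec()], the
#' expected Pearson correlation between matched centroids is
#' `1 / (1 + s^2)`; this inverts that relation.
#'
#' @param r target correlation in (0, 1].
#' @export
divergence_for_correlation <- function(r) {
  check_scalar_number(r, "r", lower = 0, upper = 1, strict_lower = TRUE)
  sqrt(1 / r - 1)
}

#' Simulate a joint embedding for two species with planted matches
#'
#' @param spec a [species_pair_spec()].
#' @return list with `embedding` (all cells of both species),
#'   `labels_a`, `labels_b` (named character vectors keyed by cell id),
#'   and `truth` (data.frame `cluster_a`, `cluster_b` of planted 1:1
#'   pairs, plus attribute `homolog_fraction`).
#' @export
simulate_species_pair <- function(spec) {
  if (!inherits(spec, "species_pair_spec"))
    abort_validation("`spec` must be a species_pair_spec")
  with_seed(spec$seed, {
    d <- spec$embedding_dim
    n_a <- spec$shared_leaves + spec$a_only_leaves
    n_b <- spec$shared_leaves + spec$b_only_leaves
    base <- matrix(stats::rnorm(spec$shared_leaves * d), ncol = d)
    cent_a <- rbind(
      base + matrix(stats::rnorm(spec$shared_leaves * d,
                                 sd = spec$divergence_sd), ncol = d),
      matrix(stats::rnorm(spec$a_only_leaves * d), ncol = d)
    )
    cent_b <- rbind(
      base + matrix(stats::rnorm(spec$shared_leaves * d,
                                 sd = spec$divergence_sd), ncol = d),
      matrix(stats::rnorm(spec$b_only_leaves * d), ncol = d)
    )
    rownames(cent_a) <- sprintf("A-%d", seq_len(n_a))
    rownames(cent_b) <- sprintf("B-%d", seq_len(n_b))
    draw_cells <- function(cent, prefix) {
      n_cl <- nrow(cent)
      n_cells <- n_cl * spec$cells_per_leaf
      cl <- rep(seq_len(n_cl), each = spec$cells_per_leaf)
      emb <- cent[cl, , drop = FALSE] +
        matrix(stats::rnorm(n_cells * d, sd = spec$noise_sd), ncol = d)
      ids <- sprintf("%s_cell_%05d", prefix, seq_len(n_cells))
      rownames(emb) <- ids
      labels <- stats::setNames(rownames(cent)[cl], ids)
      list(emb = emb, labels = labels)
    }
    a <- draw_cells(cent_a, "a")
    b <- draw_cells(cent_b, "b")
    truth <- data.frame(
      cluster_a = sprintf("A-%d", seq_len(spec$shared_leaves)),
      cluster_b = sprintf("B-%d", seq_len(spec$shared_leaves)),
      stringsAsFactors = FALSE
    )
    attr(truth, "homolog_fraction") <- spec$homolog_fraction
    list(embedding = rbind(a$emb, b$emb),
         labels_a = a$labels, labels_b = b$labels, truth = truth)
  })
}

#' Specification of a planted spatial abundance map
#'
#' @param n_regions,spots_per_region,n_clusters dimensions.
#' @param affinity clusters x regions nonnegative matrix; row `c` is the
#'   expected abundance profile of cluster `c` across regions. Rownames
#'   (cluster ids) and colnames (region ids) are used if present.
#' @param noise_sd sd of additive Gaussian spot noise (clipped at 0).
#' @param seed RNG seed.
#' @export
spatial_spec <- function(n_regions, spots_per_region, n_clusters, affinity,
                         noise_sd = 0.2, seed = 1L) {
  n_regions <- check_count(n_regions, "n_regions")
  spots_per_region <- check_count(spots_per_region, "spots_per_region")
  n_clusters <- check_count(n_clusters, "n_clusters")
  affinity <- as.matrix(affinity)
  if (!identical(dim(affinity), c(n_clusters, n_regions)))
    abort_validation("`affinity` must be %d x %d", n_clusters, n_regions)
  if (any(!is.finite(affinity)) || any(affinity < 0))
    abort_validation("`affinity` must be finite and nonnegative")
  if (is.null(rownames(affinity)))
    rownames(affinity) <- sprintf("K%d", seq_len(n_clusters))
  if (is.null(colnames(affinity)))
    colnames(affinity) <- sprintf("R%d", seq_len(n_regions))
  structure(list(
    n_regions = n_regions, spots_per_region = spots_per_region,
    n_clusters = n_clusters, affinity = affinity,
    noise_sd = check_scalar_number(noise_sd, "noise_sd", lower = 0,
                                   strict_lower = TRUE),
    seed = check_count(seed, "seed", lower = -.Machine$integer.max)
  ), class = "spatial_spec")
}

#' Simulate spot-by-cluster abundances with planted regions
#'
#' Spot abundance of cluster `c` in region `r` is
#' `affinity[c, r] + N(0, noise_sd)`, clipped at zero. The truth map
#' assigns a cluster to its unique argmax region, or `NA` when the
#' affinity row is flat (or its maximum is tied).
#'
#' @param spec a [spatial_spec()].
#' @return list with `abundance` (spots x clusters matrix), `regions`
#'   (named character, spot -> region) and `truth` (named character,
#'   cluster -> region or NA).
#' @export
simulate_spatial <- function(spec) {
  if (!inherits(spec, "spatial_spec"))
    abort_validation("`spec` must be a spatial_spec")
  with_seed(spec$seed, {
    regions <- colnames(spec$affinity)
    clusters <- rownames(spec$affinity)
    n_spots <- spec$n_regions * spec$spots_per_region
    region_of_spot <- rep(regions, each = spec$spots_per_region)
    spot_ids <- sprintf("spot_%05d", seq_len(n_spots))
    ab <- t(spec$affinity[, region_of_spot, drop = FALSE])
    ab <- ab + matrix(stats::rnorm(length(ab), sd = spec$noise_sd),
                      nrow = nrow(ab))
    ab[ab < 0] <- 0
    dimnames(ab) <- list(spot_ids, clusters)
    truth <- vapply(clusters, function(cl) {
      row <- spec$affinity[cl, ]
      if (diff(range(row)) == 0) return(NA_character_)
      top <- which(row == max(row))
      if (length(top) > 1L) NA_character_ else regions[top]
    }, character(1))
    list(abundance = ab,
         regions = stats::setNames(region_of_spot, spot_ids),
         truth = truth)
  })
}

#' Simulate specificity and gene-rank tables with planted effector genes
#'
#' Builds a gene-by-cell-type specificity matrix and a ranked gene
#' association table such that exactly the planted genes satisfy both
#' effector criteria (specificity above the per-cell-type percentile
#' cutoff in at least one cell type, and association rank within the top
#' `top_n`); every other gene fails at least one criterion by
#' construction, which the generator verifies before returning.
#'
#' @param n_genes,n_celltypes table dimensions.
#' @param planted_effectors character vector of gene ids drawn from
#'   `sprintf("g%05d", 1:n_genes)`; may be empty.
#' @param seed RNG seed.
#' @param specificity_percentile,top_n the selection thresholds the
#'   planted truth is constructed against.
#' @return list with `specificity` (matrix, values in \[0, 1\]) and
#'   `ranks` (data.frame gene, statistic, rank; ranks are a permutation
#'   of `1:n_genes` with 1 = strongest association).
#' @export
simulate_gwas_tables <- function(n_genes, n_celltypes, planted_effectors,
                                 seed = 1L, specificity_percentile = 95,
                                 top_n = 1000L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_celltypes <- check_count(n_celltypes, "n_celltypes")
  top_n <- check_count(top_n, "top_n")
  if (top_n > n_genes) abort_validation("top_n exceeds n_genes")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  planted_effectors <- as.character(planted_effectors)
  if (!all(planted_effectors %in% gene_ids))
    abort_validation("planted_effectors must be ids among g00001..g%05d",
                     n_genes)
  if (length(planted_effectors) > top_n)
    abort_validation("more planted effectors than top_n ranks")
  with_seed(seed, {
    ct_ids <- sprintf("ct%02d", seq_len(n_celltypes))
    spec <- matrix(stats::runif(n_genes * n_celltypes, 0.01, 0.6),
                   nrow = n_genes, dimnames = list(gene_ids, ct_ids))
    spec[sample(length(spec), round(0.2 * length(spec)))] <- 0

    rank_of <- integer(n_genes)
    names(rank_of) <- gene_ids
    planted_idx <- match(planted_effectors, gene_ids)
    top_ranks <- sample(top_n, length(planted_idx))
    rank_of[planted_idx] <- top_ranks
    rest <- setdiff(seq_len(n_genes), planted_idx)
    rank_of[rest] <- sample(setdiff(seq_len(n_genes), top_ranks))

    # decoys: non-planted genes holding a top rank must fail specificity
    decoys <- which(rank_of <= top_n)
    decoys <- setdiff(decoys, planted_idx)
    spec[decoys, ] <- stats::runif(length(decoys) * n_celltypes, 0.01, 0.1)
    # planted genes exceed the cutoff in one random cell type each
    if (length(planted_idx)) {
      own_ct <- sample(n_celltypes, length(planted_idx), replace = TRUE)
      spec[cbind(planted_idx, own_ct)] <-
        stats::runif(length(planted_idx), 0.95, 1)
    }

    cutoffs <- apply(spec, 2, function(v)
      stats::quantile(v[v > 0], specificity_percentile / 100, names = FALSE))
    passes <- sweep(spec, 2, cutoffs, ">")
    ok_planted <- all(rowSums(passes[planted_idx, , drop = FALSE]) >= 1)
    ok_decoys <- !length(decoys) ||
      all(rowSums(passes[decoys, , drop = FALSE]) == 0)
    if (!ok_planted || !ok_decoys)
      stop("internal error: planted effector construction failed")

    stat <- sort(stats::rchisq(n_genes, df = 1), decreasing = TRUE)
    ranks <- data.frame(gene = gene_ids,
                        statistic = stat[rank_of],
                        rank = as.integer(rank_of),
                        stringsAsFactors = FALSE)
    list(specificity = spec, ranks = ranks)
  })
}
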
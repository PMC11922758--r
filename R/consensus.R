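#' k-nearest-neighbour graph of an embedding
#'
#' Undirected union of each point's `k` nearest Euclidean neighbours
#' (unweighted simple graph), the substrate for Leiden clustering.
#'
#' @param embedding cells x dims matrix with cell id rownames.
#' @param k neighbours per cell (must be < number of cells).
#' @return an igraph graph whose vertex names are the cell ids.
#' @export
knn_graph <- function(embedding, k = 15L) {
  n <- nrow(embedding)
  k <- check_count(k, "k")
  if (k >= n) abort_validation("k_neighbors (%d) must be < n_cells (%d)", k, n)
  if (all(apply(embedding, 2, function(v) diff(range(v)) == 0)))
    warning("embedding is degenerate (constant rows); single-cluster ",
            "partitions are expected")
  d <- as.matrix(stats::dist(embedding))
  nbrs <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nbrs)), x = 1,
                              dims = c(n, n))
  adj <- (adj + Matrix::t(adj)) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- rownames(embedding) %||% as.character(seq_len(n))
  g
}

#' Run a Leiden clustering ensemble at one resolution
#'
#' Builds (or reuses) a shared kNN graph and runs Leiden community
#' detection `n_runs` times with seeds `base_seed + 0 .. n_runs - 1`,
#' producing one full partition per run. Repeated runs at several
#' resolutions, condensed by [consensus_partition()], are the robust
#' substitute for a single clustering run.
#'
#' @param embedding cells x dims matrix (ignored if `graph` is given).
#' @param resolution Leiden resolution parameter (modularity objective).
#' @param n_runs ensemble size (the reference analysis used 100; 20 is
#'   a practical default at desk scale).
#' @param k_neighbors kNN graph degree.
#' @param base_seed seed of the first run.
#' @param graph optional precomputed [knn_graph()] (shared across
#'   resolutions).
#' @return an object of class `label_ensemble`: list with `resolution`,
#'   `labels` (cells x runs integer matrix), `seeds`, `k_neighbors`.
#' @export
run_leiden_ensemble <- function(embedding, resolution, n_runs = 20L,
                                k_neighbors = 15L, base_seed = 1L,
                                graph = NULL) {
  n_runs <- check_count(n_runs, "n_runs")
  check_scalar_number(resolution, "resolution", lower = 0,
                      strict_lower = TRUE)
  if (is.null(graph)) graph <- knn_graph(embedding, k_neighbors)
  seeds <- base_seed + seq_len(n_runs) - 1L
  labels <- vapply(seeds, function(s) {
    as.integer(with_seed(s, igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = 5L))))
  }, integer(igraph::vcount(graph)))
  rownames(labels) <- igraph::V(graph)$name
  structure(list(resolution = resolution, labels = labels, seeds = seeds,
                 k_neighbors = k_neighbors),
            class = "label_ensemble")
}

#' Co-association matrix of a label ensemble
#'
#' Entry (i, j) is the fraction of ensemble runs in which cells i and j
#' share a cluster.
#'
#' @param ensemble a `label_ensemble` or a cells x runs label matrix.
#' @export
coassociation_matrix <- function(ensemble) {
  labels <- if (inherits(ensemble, "label_ensemble")) ensemble$labels
            else as.matrix(ensemble)
  n <- nrow(labels)
  C <- matrix(0, n, n)
  for (r in seq_len(ncol(labels)))
    C <- C + outer(labels[, r], labels[, r], "==")
  C / ncol(labels)
}

#' Co-association agreement of a flat partition with an ensemble
#'
#' Mean over unordered cell pairs of `C_ij` when the partition puts the
#' pair together and `1 - C_ij` when it splits them; 1 means the
#' partition reproduces every pairwise ensemble vote.
#'
#' @param labels flat partition.
#' @param C co-association matrix from [coassociation_matrix()].
#' @export
coassociation_agreement <- function(labels, C) {
  n <- length(labels)
  same <- outer(labels, labels, "==")
  up <- upper.tri(C)
  mean(ifelse(same[up], C[up], 1 - C[up]))
}

#' Consensus partition of a Leiden ensemble (hybrid bipartite graph)
#'
#' Hybrid bipartite graph formulation: cells and per-run clusters form
#' the two sides of a bipartite graph with an edge wherever a cell
#' belongs to a run-cluster. The graph is partitioned by spectral
#' embedding of the degree-normalized bipartite adjacency (top-`k`
#' left singular vectors, rows normalized) followed by k-means on the
#' cell vertices, then polished by a greedy single-cell pass to a local
#' optimum of the co-association agreement. `k` defaults to the median
#' per-run cluster count.
#'
#' @param ensemble a `label_ensemble` (or cells x runs label matrix).
#' @param k number of consensus clusters; default median cluster count
#'   across runs.
#' @param refine run the greedy co-association polish (skipped above
#'   `max_refine_cells` cells, where the n x n co-association matrix
#'   gets large).
#' @param max_refine_cells size cap for the polish step.
#' @return integer vector of consensus labels (1..k, named by cell id).
#' @export
consensus_partition <- function(ensemble, k = NULL, refine = TRUE,
                                max_refine_cells = 5000L) {
  labels <- if (inherits(ensemble, "label_ensemble")) ensemble$labels
            else as.matrix(ensemble)
  if (!ncol(labels)) abort_validation("ensemble is empty")
  n <- nrow(labels)
  counts_per_run <- apply(labels, 2L, function(v) length(unique(v)))
  if (is.null(k)) k <- as.integer(round(stats::median(counts_per_run)))
  k <- check_count(k, "k")
  if (k > n) abort_validation("k (%d) exceeds n_cells (%d)", k, n)
  cell_ids <- rownames(labels) %||% as.character(seq_len(n))

  if (ncol(labels) == 1L)
    return(stats::setNames(match(labels[, 1L], unique(labels[, 1L])),
                           cell_ids))

  # bipartite incidence: cells x (run, cluster) vertices
  blocks <- lapply(seq_len(ncol(labels)), function(r) {
    f <- factor(labels[, r])
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                         dims = c(n, nlevels(f)))
  })
  B <- do.call(cbind, blocks)
  d1 <- Matrix::rowSums(B)
  d2 <- Matrix::colSums(B)
  A <- Matrix::Diagonal(x = 1 / sqrt(d1)) %*% B %*%
    Matrix::Diagonal(x = 1 / sqrt(d2))
  k_eff <- min(k, ncol(A))
  U <- svd(as.matrix(A), nu = k_eff, nv = 0)$u
  norms <- sqrt(rowSums(U^2))
  U <- U / pmax(norms, .Machine$double.eps)

  uniq <- unique(round(U, 10))
  lab <- if (nrow(uniq) <= k) {
    match(apply(round(U, 10), 1L, paste, collapse = ","),
          apply(uniq, 1L, paste, collapse = ","))
  } else {
    # MacQueen avoids spurious Quick-TRANSfer warnings on the many
    # duplicate rows a unanimous ensemble produces
    km <- with_seed(1000003L + n + k,
                    stats::kmeans(U, centers = k, nstart = 10L,
                                  iter.max = 100L,
                                  algorithm = "MacQueen"))
    km$cluster
  }

  if (refine && n <= max_refine_cells) {
    # multi-start greedy polish: spectral solution plus (deduplicated)
    # run labelings as candidate starts, best by co-association agreement
    C <- coassociation_matrix(labels)
    starts <- list(lab)
    seen <- character(0)
    for (r in seq_len(ncol(labels))) {
      cand <- match(labels[, r], unique(labels[, r]))
      if (max(cand) > k) next
      key <- paste(cand, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      starts[[length(starts) + 1L]] <- cand
      if (length(starts) >= 12L) break
    }
    refined <- lapply(starts, refine_coassociation, C = C, k = k)
    scores <- vapply(refined, coassociation_agreement, numeric(1), C = C)
    lab <- refined[[which.max(scores)]]
  }
  lab <- match(lab, unique(lab))
  stats::setNames(as.integer(lab), cell_ids)
}

# Greedy single-cell reassignment to a local optimum of the
# co-association agreement; sequential in cell order for determinism.
refine_coassociation <- function(lab, C, k) {
  n <- length(lab)
  C2 <- 2 * C - 1
  H <- matrix(0, n, k)
  H[cbind(seq_len(n), lab)] <- 1
  M <- C2 %*% H  # M[i, l] = sum over j in cluster l of (2C_ij - 1)
  for (pass in seq_len(20L)) {
    moved <- 0L
    for (i in seq_len(n)) {
      scores <- M[i, ] - ifelse(seq_len(k) == lab[i], C2[i, i], 0)
      best <- which.max(scores)
      if (best != lab[i] && scores[best] > scores[lab[i]] + 1e-12) {
        old <- lab[i]
        M[, old] <- M[, old] - C2[, i]
        M[, best] <- M[, best] + C2[, i]
        lab[i] <- best
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
  }
  lab
}
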
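# Independent oracles, deliberately implemented apart from the package
# code paths they check.

# Pairwise co-association agreement, written from the definition.
oracle_agreement <- function(labels, run_labels) {
  n <- length(labels)
  tot <- 0; npair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    co <- mean(run_labels[i, ] == run_labels[j, ])
    tot <- tot + if (labels[i] == labels[j]) co else 1 - co
    npair <- npair + 1
  }
  tot / npair
}

# Exhaustive optimum of the co-association agreement over all
# assignments of n cells to at most k labels (vectorized enumeration).
oracle_best_agreement <- function(run_labels, k) {
  n <- nrow(run_labels)
  L <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))  # k^n labelings
  tot <- numeric(nrow(L)); npair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    co <- mean(run_labels[i, ] == run_labels[j, ])
    tot <- tot + ifelse(L[, i] == L[, j], co, 1 - co)
    npair <- npair + 1
  }
  max(tot) / npair
}

# Brute-force re-implementation of the match-graph star-pruning rule on
# an adjacency weight matrix (rows = species A, cols = species B, NA =
# no edge). Same node order convention as documented: lexical (species,
# id), sweeps to a fixed point.
oracle_prune_matrix <- function(W) {
  a_ids <- rownames(W); b_ids <- colnames(W)
  repeat {
    changed <- FALSE
    for (a in sort(a_ids)) {
      nb <- which(!is.na(W[a, ]))
      if (length(nb) < 2) next
      if (any(colSums(!is.na(W[, nb, drop = FALSE])) >= 2)) {
        keep_val <- max(W[a, nb])
        cand <- nb[W[a, nb] == keep_val]
        keep <- cand[order(b_ids[cand])][1]
        W[a, setdiff(nb, keep)] <- NA
        changed <- TRUE
      }
    }
    for (b in sort(b_ids)) {
      nb <- which(!is.na(W[, b]))
      if (length(nb) < 2) next
      if (any(rowSums(!is.na(W[nb, , drop = FALSE])) >= 2)) {
        keep_val <- max(W[nb, b])
        cand <- nb[W[nb, b] == keep_val]
        keep <- cand[order(a_ids[cand])][1]
        W[setdiff(nb, keep), b] <- NA
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  W
}

match_graph_to_matrix <- function(graph) {
  W <- matrix(NA_real_, length(graph$nodes_a), length(graph$nodes_b),
              dimnames = list(graph$nodes_a, graph$nodes_b))
  if (nrow(graph$edges))
    W[cbind(graph$edges$a, graph$edges$b)] <- graph$edges$adj
  W
}

# Stratified permutation test for the combined weighted rank-sum
# statistic (its own implementation of the numerator). Ranks within a
# stratum are permutation-invariant, so they are computed once and each
# permutation just redraws which positions are "target".
oracle_perm_p <- function(values, is_target, stratum, B = 10000) {
  strata <- lapply(unique(stratum), function(s) {
    sel <- which(stratum == s)
    list(r = rank(values[sel]), n1 = sum(is_target[sel]),
         n = length(sel), tgt = is_target[sel])
  })
  stat_of <- function(pick) {   # pick: list of target index sets
    tot <- 0
    for (q in seq_along(strata)) {
      st <- strata[[q]]
      tot <- tot + (sum(st$r[pick[[q]]]) - st$n1 * (st$n + 1) / 2) /
        (st$n + 1)
    }
    tot
  }
  obs <- stat_of(lapply(strata, function(st) which(st$tgt)))
  cnt <- 0
  for (b in seq_len(B)) {
    pick <- lapply(strata, function(st) sample(st$n, st$n1))
    if (abs(stat_of(pick)) >= abs(obs) - 1e-12) cnt <- cnt + 1
  }
  (cnt + 1) / (B + 1)
}

# Random bipartite weighted graph as a match_graph (for star-property
# checks), with adjusted weights in (threshold, 1].
random_match_graph <- function(n_a, n_b, p_edge = 0.4, threshold = 0.7) {
  a_ids <- sprintf("A-%d", seq_len(n_a))
  b_ids <- sprintf("B-%d", seq_len(n_b))
  edges <- expand.grid(a = a_ids, b = b_ids, stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < p_edge, , drop = FALSE]
  edges$r <- runif(nrow(edges), threshold, 1)
  edges$adj <- edges$r
  edges$type <- rep(NA_character_, nrow(edges))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes_a = a_ids, nodes_b = b_ids),
            class = "match_graph")
}

# Small labeled cell table for QC tests.
make_cells <- function(umi, mito, doublet = FALSE, donor = "D1",
                       batch = "B1", label = NULL) {
  n <- max(length(umi), length(mito), length(doublet))
  df <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    umi_count = rep_len(umi, n),
    mito_fraction = rep_len(mito, n),
    donor_id = rep_len(donor, n),
    sample_id = rep_len(paste0(donor, ".", batch), n),
    batch_id = rep_len(batch, n),
    doublet_flag = rep_len(doublet, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(label)) df$C1 <- rep_len(label, n)
  df
}

skip_if_no_mclust <- function() testthat::skip_if_not_installed("mclust")
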
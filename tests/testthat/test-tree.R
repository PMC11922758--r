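nested_labels <- function() {
  cells <- sprintf("c%03d", 1:60)
  cbind(C1 = rep(c("a", "b"), each = 30),
        C2 = rep(c("a1", "a2", "b1", "b2"),  c(20, 10, 15, 15))) |>
    (\(m) { rownames(m) <- cells; m })()
}

test_that("cluster_tree validates nestedness and exposes structure", {
  labels <- nested_labels()
  emb <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(rownames(labels), NULL))
  tree <- cluster_tree(labels, emb)
  expect_equal(tree$nodes$parent[tree$nodes$node_id == "a1"], "a")
  expect_setequal(tree_siblings(tree, "a1"), "a2")
  expect_setequal(tree_children(tree, "b"), c("b1", "b2"))
  expect_equal(length(tree_node_cells(tree, "a1")), 20)
  # sibling cell sets partition the parent
  expect_setequal(c(tree_node_cells(tree, "a1"), tree_node_cells(tree, "a2")),
                  tree_node_cells(tree, "a"))
  bad <- labels; bad[1, "C1"] <- "b"
  expect_error(cluster_tree(bad), "not nested")
})

test_that("already-nested labelings reconcile unchanged at zero cost", {
  labels <- nested_labels()
  emb <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(rownames(labels), NULL))
  tree <- build_tree(list(labels[, 1], labels[, 2]), emb)
  expect_equal(tree$reconciliation_cost, 0)
  expect_equal(unname(tree$labels[, 1]), paste0("C1-", labels[, 1]))
  expect_equal(unname(tree$labels[, 2]), paste0("C2-", labels[, 2]))
})

test_that("a 60/40 split cluster attaches to the plurality parent", {
  cells <- sprintf("c%03d", 1:200)
  coarse <- c(rep("p1", 60), rep("p2", 40), rep("p1", 50), rep("p2", 50))
  fine <- c(rep("q", 100), rep("r", 50), rep("s", 50))
  emb <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(cells, NULL))
  names(coarse) <- names(fine) <- cells
  tree <- build_tree(list(coarse, fine), emb)
  # q goes to p1; its 40 p2 cells are relabeled along the majority path
  expect_equal(tree$nodes$parent[tree$nodes$node_id == "C2-q"], "C1-p1")
  expect_equal(tree$reconciliation_cost, 40)
  expect_equal(unname(tree$labels[70, 1]), "C1-p1")
  # nestedness invariant holds after reconciliation
  expect_s3_class(cluster_tree(tree$labels), "cluster_tree")
})

test_that("a single resolution yields a one-level tree", {
  cells <- sprintf("c%02d", 1:30)
  lab <- setNames(rep(c("x", "y", "z"), each = 10), cells)
  emb <- matrix(rnorm(90), 30, 3, dimnames = list(cells, NULL))
  tree <- build_tree(list(lab), emb)
  expect_equal(tree$levels, "C1")
  expect_true(all(is.na(tree$nodes$parent)))
})

test_that("pruning merges failing nodes into the nearest sibling", {
  # three siblings on a line; A is donor-dominated, B at distance 1.0,
  # C at distance 2.5 -> A must merge into B
  cells <- sprintf("c%03d", 1:180)
  emb <- cbind(rep(c(0, 1, 2.5), each = 60), 0)
  rownames(emb) <- cells
  labels <- matrix(rep(c("A", "B", "C"), each = 60), ncol = 1,
                   dimnames = list(cells, "C1"))
  cellt <- data.frame(cell_id = cells,
                      donor_id = c(rep("D1", 57), "D2", "D3", "D4",
                                   rep(c("D1", "D2", "D3"), 40)),
                      batch_id = "B1", stringsAsFactors = FALSE)
  tree <- cluster_tree(labels, emb)
  pruned <- prune_tree(tree, counts = NULL, cells = cellt,
                       cfg = prune_config(min_cells = 10), embedding = emb)
  log <- attr(pruned, "prune_log")
  expect_equal(log$node, "A")
  expect_equal(log$reason, "donor_fraction")
  expect_equal(log$target, "B")
  expect_equal(log$distance, 1.0)
  expect_setequal(pruned$nodes$node_id, c("B", "C"))
  # recomputed centroid of B is the mean of A+B member coordinates
  expect_equal(unname(pruned$centroids["B", 1]), 0.5)
  expect_true(attr(pruned, "converged"))
})

test_that("a tree whose nodes all pass is a fixed point of pruning", {
  sim <- simulate_hierarchy(hierarchy_spec(levels = c(2, 2),
                                           cells_per_leaf = 100,
                                           embedding_dim = 6, seed = 33))
  cnt <- simulate_counts(sim$tree, sim$cells, n_genes = 60,
                         markers_per_leaf = 6, seed = 34)
  pruned <- prune_tree(sim$tree, cnt$counts, sim$cells, prune_config(),
                       embedding = sim$embedding)
  expect_equal(nrow(attr(pruned, "prune_log")), 0)
  expect_identical(pruned$labels, sim$tree$labels)
})

test_that("an undersized node is merged (min_cells criterion)", {
  sim <- simulate_hierarchy(hierarchy_spec(levels = c(3), cells_per_leaf = 100,
                                           embedding_dim = 6, seed = 35))
  labels <- sim$tree$labels
  small <- which(labels[, 1] == "C1-1")
  labels[small[-(1:40)], 1] <- "C1-2"      # shrink C1-1 to 40 cells
  tree <- cluster_tree(labels, sim$embedding)
  pruned <- prune_tree(tree, counts = NULL, cells = sim$cells,
                       cfg = prune_config(), embedding = sim$embedding)
  log <- attr(pruned, "prune_log")
  expect_true("C1-1" %in% log$node)
  expect_false("C1-1" %in% pruned$nodes$node_id)
})

test_that("expression-percentile cluster selection matches a brute-force cutoff", {
  # 20 clusters with detection fractions 0.00, 0.05, ..., 0.95
  n_per <- 20
  fracs <- seq(0, 0.95, by = 0.05)
  counts <- do.call(cbind, lapply(fracs, function(f) {
    v <- c(rep(1, round(f * n_per)), rep(0, n_per - round(f * n_per)))
    matrix(v, nrow = 1)
  }))
  dimnames(counts) <- list("goi", sprintf("c%03d", seq_len(ncol(counts))))
  labels <- rep(sprintf("k%02d", 1:20), each = n_per)
  got <- select_clusters_by_expression(counts, labels, "goi", 95)
  # independent percentile computation (sort + linear interpolation)
  s <- sort(fracs); h <- (length(s) - 1) * 0.95 + 1
  cutoff <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  expect_setequal(got, sprintf("k%02d", which(fracs >= cutoff)))
  # percentile 0: every cluster clears the minimum
  expect_length(select_clusters_by_expression(counts, labels, "goi", 0), 20)
  # gene expressed nowhere: empty selection
  zero <- counts; zero["goi", ] <- 0
  expect_length(select_clusters_by_expression(zero, labels, "goi", 95), 0)
  expect_error(select_clusters_by_expression(counts, labels, "nope", 95),
               "not present")
})
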
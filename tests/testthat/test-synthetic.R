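test_that("hierarchy generator is deterministic and plants exact geometry", {
  spec <- hierarchy_spec(levels = c(2, 2), cells_per_leaf = 100,
                         embedding_dim = 10, separation = 10, noise_sd = 1,
                         seed = 7)
  a <- simulate_hierarchy(spec)
  b <- simulate_hierarchy(spec)
  expect_identical(a, b)

  # sibling leaf centroid distances equal separation * decay exactly
  planted <- a$tree$centroids
  s2 <- 10 * 0.7
  d12 <- sqrt(sum((planted["C2-1", ] - planted["C2-2", ])^2))
  expect_equal(d12, s2, tolerance = 1e-10)

  # empirical centroids match planted within 3 standard errors
  for (leaf in c("C2-1", "C2-4")) {
    cells <- tree_node_cells(a$tree, leaf)
    emp <- colMeans(a$embedding[cells, ])
    se <- 1 / sqrt(length(cells))
    expect_lt(sqrt(sum((emp - planted[leaf, ])^2)), 3 * se * sqrt(10))
  }

  # empirical sibling distance approx planted separation at that level
  emp_d <- sqrt(sum((colMeans(a$embedding[tree_node_cells(a$tree, "C2-1"), ]) -
                     colMeans(a$embedding[tree_node_cells(a$tree, "C2-2"), ]))^2))
  expect_lt(abs(emp_d - s2), 0.5)   # 3 s.e. of a centroid-pair distance

  # every cell has exactly one leaf, donor, batch
  expect_false(anyNA(a$tree$labels))
  expect_false(anyNA(a$cells$donor_id))
  expect_false(anyNA(a$cells$batch_id))
  expect_error(hierarchy_spec(levels = c(0, 2)), "levels")
})

test_that("zero separation plants no recoverable structure", {
  sim <- simulate_hierarchy(hierarchy_spec(levels = c(2), cells_per_leaf = 80,
                                           embedding_dim = 5, separation = 0,
                                           seed = 1))
  cents <- rowsum(sim$embedding, sim$tree$labels[, 1])
  cents <- cents / as.vector(table(sim$tree$labels[, 1]))
  # the two "clusters" are the same blob: centroids within noise of one another
  expect_lt(sqrt(sum((cents[1, ] - cents[2, ])^2)), 0.5)
})

test_that("count generator plants markers, batch effects and no empty cells", {
  sim <- simulate_hierarchy(hierarchy_spec(levels = c(3), cells_per_leaf = 200,
                                           embedding_dim = 4, seed = 5))
  cnt <- simulate_counts(sim$tree, sim$cells, n_genes = 50,
                         markers_per_leaf = 2, seed = 6)
  expect_identical(cnt$counts,
                   simulate_counts(sim$tree, sim$cells, 50, 2, seed = 6)$counts)
  expect_true(all(Matrix::colSums(cnt$counts) > 0))
  expect_equal(nrow(cnt$markers), 6)

  # planted 10x markers are detected at Bonferroni 0.05 (power over 20 seeds)
  hits <- 0; total <- 0
  for (s in 1:20) {
    cs <- simulate_counts(sim$tree, sim$cells, n_genes = 40,
                          markers_per_leaf = 2, seed = 100 + s)
    mk <- find_markers(cs$counts, sim$tree$labels[, 1], sim$cells$batch_id,
                       "C1-1")
    own <- cs$markers$gene[cs$markers$leaf == "C1-1"]
    hits <- hits + sum(mk$p_adj[mk$gene %in% own] < 0.05)
    total <- total + length(own)
  }
  expect_gte(hits / total, 0.9)

  expect_error(simulate_counts(sim$tree, sim$cells, n_genes = 5,
                               markers_per_leaf = 2, seed = 1),
               "exceeds n_genes")
})

test_that("null counts give only nominal marker false positives", {
  sim <- simulate_hierarchy(hierarchy_spec(levels = c(2), cells_per_leaf = 150,
                                           embedding_dim = 3, seed = 8))
  cnt <- simulate_counts(sim$tree, sim$cells, n_genes = 2000,
                         markers_per_leaf = 0, batch_effect_sd = 0.4,
                         seed = 9)
  mk <- find_markers(cnt$counts, sim$tree$labels[, 1], sim$cells$batch_id,
                     "C1-1")
  expect_lt(abs(mean(mk$p < 0.05) - 0.05), 0.02)
  expect_equal(sum(mk$p_adj < 0.05), 0)
})

test_that("species pair generator books shared and private clusters", {
  spec <- species_pair_spec(shared_leaves = 8, a_only_leaves = 5,
                            b_only_leaves = 2, cells_per_leaf = 50,
                            divergence_sd = 0, noise_sd = 0.05, seed = 3)
  sp <- simulate_species_pair(spec)
  expect_identical(sp, simulate_species_pair(spec))
  expect_equal(nrow(sp$truth), 8)
  expect_equal(length(unique(sp$labels_a)), 13)
  expect_setequal(setdiff(unique(sp$labels_a), sp$truth$cluster_a),
                  sprintf("A-%d", 9:13))

  # zero divergence: matched centroids correlate at ~1
  r <- correlate_centroids(sp$embedding, sp$labels_a, sp$labels_b)
  matched <- r[cbind(sp$truth$cluster_a, sp$truth$cluster_b)]
  expect_true(all(matched > 0.99))
  expect_error(species_pair_spec(homolog_fraction = 1.5), "homolog_fraction")
})

test_that("divergence_for_correlation inverts the perturbation model", {
  s <- divergence_for_correlation(0.9)
  sp <- simulate_species_pair(species_pair_spec(
    shared_leaves = 40, a_only_leaves = 0, b_only_leaves = 0,
    cells_per_leaf = 30, embedding_dim = 80, divergence_sd = s,
    noise_sd = 0.05, seed = 4))
  r <- correlate_centroids(sp$embedding, sp$labels_a, sp$labels_b)
  matched <- r[cbind(sp$truth$cluster_a, sp$truth$cluster_b)]
  expect_equal(mean(matched), 0.9, tolerance = 0.05)
})

test_that("spatial generator respects affinity truth rules", {
  aff <- rbind(c(5, 1, 1), c(1, 1, 1), c(2, 2, 1))
  rownames(aff) <- c("hot", "flat", "tied")
  spec <- spatial_spec(3, 10, 3, aff, noise_sd = 0.1, seed = 2)
  sp <- simulate_spatial(spec)
  expect_identical(sp, simulate_spatial(spec))
  expect_true(all(sp$abundance >= 0))
  expect_equal(unname(sp$truth["hot"]), "R1")
  expect_true(is.na(sp$truth["flat"]))
  expect_true(is.na(sp$truth["tied"]))
  expect_equal(dim(sp$abundance), c(30, 3))
  expect_error(spatial_spec(3, 10, 2, aff), "affinity")
})

test_that("gwas table generator plants exactly the requested effectors", {
  genes <- sprintf("g%05d", 1:500)
  planted <- c("g00005", "g00123", "g00400")
  gw <- simulate_gwas_tables(500, 6, planted, seed = 11, top_n = 50)
  expect_identical(gw, simulate_gwas_tables(500, 6, planted, seed = 11,
                                            top_n = 50))
  expect_setequal(gw$ranks$rank, 1:500)          # ranks are a permutation
  expect_true(all(gw$specificity >= 0 & gw$specificity <= 1))
  # statistic is monotone decreasing in rank
  o <- order(gw$ranks$rank)
  expect_true(all(diff(gw$ranks$statistic[o]) <= 0))

  sel <- select_effector_genes(gw$specificity, gw$ranks,
                               effector_config(top_n_genes = 50))
  expect_setequal(sel$gene, planted)

  # no planted effectors -> empty selection
  gw0 <- simulate_gwas_tables(500, 6, character(0), seed = 12, top_n = 50)
  sel0 <- select_effector_genes(gw0$specificity, gw0$ranks,
                                effector_config(top_n_genes = 50))
  expect_equal(nrow(sel0), 0)
})
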
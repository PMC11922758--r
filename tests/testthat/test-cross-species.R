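test_that("homolog reduction keeps the highest-similarity pair per gene", {
  tab <- data.frame(gene_a = c("gA", "gA", "gC"),
                    gene_b = c("gB1", "gB2", "gB3"),
                    similarity = c(80, 95, 50))
  out <- reduce_homologs(tab)
  expect_equal(out$gene_b[out$gene_a == "gA"], "gB2")
  expect_equal(nrow(out), 2)
  # single pair passes through
  one <- data.frame(gene_a = "x", gene_b = "y", similarity = 1)
  expect_equal(reduce_homologs(one), one)
  # tie -> lexicographically smaller partner
  tie <- data.frame(gene_a = c("gA", "gA"), gene_b = c("gZ", "gB"),
                    similarity = c(90, 90))
  expect_equal(reduce_homologs(tie)$gene_b, "gB")
  # result is injective both ways
  set.seed(7)
  big <- data.frame(gene_a = sample(sprintf("a%d", 1:20), 60, TRUE),
                    gene_b = sample(sprintf("b%d", 1:20), 60, TRUE),
                    similarity = runif(60))
  big <- big[!duplicated(big[, 1:2]), ]
  red <- reduce_homologs(big)
  expect_false(anyDuplicated(red$gene_a) > 0)
  expect_false(anyDuplicated(red$gene_b) > 0)
  dup <- data.frame(gene_a = c("x", "x"), gene_b = c("y", "y"),
                    similarity = c(1, 2))
  expect_error(reduce_homologs(dup), "duplicate")
})

test_that("shared HVG selection ranks by occurrence with variance tie-break", {
  genes <- sprintf("g%d", 1:6)
  fa <- matrix(c(1,1,1, 1,1,0, 1,0,0, 1,0,0, 0,0,0, 1,1,1), 6, 3,
               byrow = TRUE, dimnames = list(genes, NULL)) > 0
  cfg <- match_config(hvg_per_species = 3)
  # occurrence in A: g1=3, g6=3, g2=2, g3=1, g4=1, g5=0 -> top3 g1,g6,g2
  got <- select_shared_hvgs(fa, fa, cfg)
  expect_setequal(got, c("g1", "g6", "g2"))
  # tie at the boundary resolved by mean per-sample variance rank
  va <- matrix(1, 6, 3, dimnames = list(genes, NULL))
  va["g4", ] <- 5   # g4 more variable than g3 -> wins the 1-occurrence tie
  cfg2 <- match_config(hvg_per_species = 4)
  got2 <- select_shared_hvgs(fa, fa, cfg2, var_a = va, var_b = va)
  expect_true("g4" %in% got2)
  expect_false("g3" %in% got2)
  # brute-force order check (per species, then intersect)
  occ <- rowSums(fa); vr <- rowMeans(apply(-va, 2, rank))
  manual <- genes[order(-occ, vr, genes)]
  manual <- manual[occ[manual] > 0][1:4]
  expect_setequal(got2, manual)
  # a gene flagged in one species only never enters the intersection
  fb0 <- fa; fb0["g1", ] <- FALSE
  expect_false("g1" %in% select_shared_hvgs(fa, fb0, cfg))
  # disjoint flag sets: empty intersection is an error
  fb_dis <- fa & FALSE
  fb_dis["g5", ] <- TRUE   # B's only HVG is the one gene A never flags
  expect_error(select_shared_hvgs(fa, fb_dis,
                                  match_config(hvg_per_species = 6)),
               "no shared")
})

test_that("centroid correlation reproduces exact and anti-correlated cases", {
  emb <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(-1, -2, -3, -4))
  rownames(emb) <- c("a1", "a2", "b1")
  la <- c(a1 = "A-1", a2 = "A-1")
  lb <- c(b1 = "B-1")
  r <- correlate_centroids(emb, la, lb)
  expect_equal(unname(r["A-1", "B-1"]), -1)
  lb2 <- c(b1 = "B-1")
  emb2 <- emb; emb2["b1", ] <- c(1, 2, 3, 4)
  expect_equal(unname(correlate_centroids(emb2, la, lb2)["A-1", "B-1"]), 1)
  expect_error(correlate_centroids(emb[, 1:2], la, lb), "dimension")
})

test_that("random independent centroids rarely exceed |r| = 0.5 in 80 dims", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    sp <- simulate_species_pair(species_pair_spec(
      shared_leaves = 0, a_only_leaves = 10, b_only_leaves = 10,
      cells_per_leaf = 20, embedding_dim = 80, noise_sd = 0.1, seed = seed))
    r <- correlate_centroids(sp$embedding, sp$labels_a, sp$labels_b)
    hits <- hits + sum(abs(r) >= 0.5); total <- total + length(r)
  }
  expect_lt(hits / total, 0.01)
})

test_that("correlation adjustment implements 2r - max on both axes", {
  r <- matrix(c(0.9, 0.8, 0.1,
                0.2, 0.6, 0.3,
                0.1, 0.2, 0.85), 3, 3, byrow = TRUE)
  adj <- adjust_correlations(r)
  # independent recomputation, elementwise
  for (i in 1:3) for (j in 1:3) {
    expected <- min(2 * r[i, j] - max(r[i, ]), 2 * r[i, j] - max(r[, j]))
    expect_equal(adj[i, j], expected)
  }
  # a global row+column maximum is a fixed point
  expect_equal(adj[1, 1], 0.9)
  # worked 2x1 case: row (0.9, 0.8) where 0.8 is also its column max
  r2 <- matrix(c(0.9, 0.8), 1, 2)
  expect_equal(adjust_correlations(r2)[1, 2], 0.7)
  # one-sided modes
  expect_equal(adjust_correlations(r, "row")[1, 2], 2 * 0.8 - 0.9)
})

test_that("match graph gates strictly and prunes to stars", {
  adj <- matrix(c(0.9, 0.7, 0.2), 1, 3,
                dimnames = list("A-1", c("B-1", "B-2", "B-3")))
  g <- build_match_graph(adj, match_config())
  expect_equal(nrow(g$edges), 1)        # 0.7 exactly is NOT an edge
  # threshold sweep: edge count non-increasing
  set.seed(8)
  adj2 <- matrix(runif(30, -1, 1), 5, 6,
                 dimnames = list(sprintf("A-%d", 1:5), sprintf("B-%d", 1:6)))
  counts <- sapply(c(-0.5, 0, 0.5, 0.9), function(th)
    nrow(build_match_graph(adj2, match_config(adjusted_threshold = th))$edges))
  expect_true(all(diff(counts) <= 0))

  # spec'd hand trace: h1-m1 (.9), h1-m2 (.8), m1-h2 (.85)
  adj3 <- matrix(c(0.9, 0.8,
                   0.85, NA), 2, 2, byrow = TRUE,
                 dimnames = list(c("h1", "h2"), c("m1", "m2")))
  adj3[is.na(adj3)] <- -1
  g3 <- prune_match_graph(build_match_graph(adj3, match_config()))
  e3 <- g3$edges
  expect_setequal(paste(e3$a, e3$b), c("h1 m1", "h2 m1"))
  expect_true(all(e3$type == "M:1"))

  # an isolated 1:1 edge is untouched; an exclusive star is kept as 1:N
  adj4 <- matrix(-1, 3, 4, dimnames = list(sprintf("A-%d", 1:3),
                                           sprintf("B-%d", 1:4)))
  adj4["A-1", "B-1"] <- 0.8
  adj4["A-2", c("B-2", "B-3", "B-4")] <- c(0.9, 0.85, 0.8)
  g4 <- prune_match_graph(build_match_graph(adj4, match_config()))
  types <- setNames(g4$edges$type, paste(g4$edges$a, g4$edges$b))
  expect_equal(unname(types["A-1 B-1"]), "1:1")
  expect_equal(unname(types["A-2 B-2"]), "1:N")
  expect_equal(nrow(g4$edges), 4)
})

test_that("pruned graphs are stars and match the brute-force rule", {
  set.seed(9)
  for (i in 1:100) {
    g <- random_match_graph(sample(2:6, 1), sample(2:6, 1))
    p <- prune_match_graph(g)
    # star property: no two adjacent nodes both of degree >= 2
    da <- table(p$edges$a); db <- table(p$edges$b)
    for (k in seq_len(nrow(p$edges)))
      expect_false(da[[p$edges$a[k]]] >= 2 && db[[p$edges$b[k]]] >= 2)
    # never adds edges
    expect_lte(nrow(p$edges), nrow(g$edges))
    # edge-for-edge agreement with the independent matrix implementation
    W <- oracle_prune_matrix(match_graph_to_matrix(g))
    kept <- which(!is.na(W), arr.ind = TRUE)
    expect_setequal(paste(p$edges$a, p$edges$b),
                    paste(rownames(W)[kept[, 1]], colnames(W)[kept[, 2]]))
  }
})

test_that("match summaries cover every cluster and order partners by r", {
  g <- random_match_graph(4, 4)
  p <- prune_match_graph(g)
  s <- match_summary(p, sprintf("A-%d", 1:5), sprintf("B-%d", 1:5))
  expect_equal(nrow(s), 10)                        # every cluster once
  expect_true(s$unmatched[s$cluster == "A-5" & s$species == "A"])
  for (k in which(!s$unmatched)) {
    partners <- strsplit(s$partners[k], ",")[[1]]
    if (length(partners) > 1) {
      e <- p$edges
      rs <- if (s$species[k] == "A") {
        sub <- e[e$a == s$cluster[k], ]
        sub$r[match(partners, sub$b)]
      } else {
        sub <- e[e$b == s$cluster[k], ]
        sub$r[match(partners, sub$a)]
      }
      expect_true(all(diff(rs) <= 0))
    }
  }
  # empty graph: everything unmatched
  empty <- build_match_graph(matrix(-1, 2, 2,
      dimnames = list(c("A-1", "A-2"), c("B-1", "B-2"))), match_config())
  s0 <- match_summary(prune_match_graph(empty))
  expect_true(all(s0$unmatched))
})
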
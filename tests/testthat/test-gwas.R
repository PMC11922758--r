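small_counts <- function(n_genes = 20, n_cells = 60, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 2), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("c%02d", 1:n_cells)))
  list(counts = m, labels = rep(c("ct1", "ct2", "ct3"), length.out = n_cells))
}

test_that("bootstrap aggregation is an elementwise mean over subsets", {
  d <- small_counts()
  S <- matrix(0.5, 20, 3, dimnames = list(rownames(d$counts),
                                          c("ct1", "ct2", "ct3")))
  const_fn <- function(counts, labels) S
  cfg <- effector_config(n_subsets = 4, subset_size = 30)
  expect_equal(bootstrap_specificity(d$counts, d$labels, const_fn, cfg), S)

  # degenerate bootstrap: one subset of all cells = plain spec_fn
  cfg1 <- effector_config(n_subsets = 1, subset_size = 60)
  expect_equal(bootstrap_specificity(d$counts, d$labels,
                                     specificity_mean_norm, cfg1),
               specificity_mean_norm(d$counts, d$labels))

  # two known matrices -> their average
  A <- S; A[] <- 0.2; B <- S; B[] <- 0.8
  i <- 0
  ab_fn <- function(counts, labels) { i <<- i + 1; if (i == 1) A else B }
  cfg2 <- effector_config(n_subsets = 2, subset_size = 30)
  expect_equal(bootstrap_specificity(d$counts, d$labels, ab_fn, cfg2),
               (A + B) / 2)

  bad_fn <- function(counts, labels) S * 3
  expect_error(bootstrap_specificity(d$counts, d$labels, bad_fn, cfg),
               "outside")
  expect_error(bootstrap_specificity(d$counts, d$labels, const_fn,
                                     effector_config(subset_size = 1000)),
               "exceeds")
})

test_that("bootstrap of a linear statistic matches the full-data value", {
  d <- small_counts(n_genes = 10, n_cells = 300, seed = 2)
  # detection-rate statistic is linear in cells, squashed into [0, 1]
  det_fn <- function(counts, labels) {
    sapply(sort(unique(labels)), function(l)
      rowMeans(counts[, labels == l, drop = FALSE] > 0))
  }
  full <- det_fn(d$counts, d$labels)
  boot <- bootstrap_specificity(d$counts, d$labels, det_fn,
                                effector_config(n_subsets = 50,
                                                subset_size = 150),
                                seed = 3)
  expect_lt(max(abs(boot - full)), 0.05)
})

test_that("cell-type prioritization applies the strict Bonferroni gate", {
  p <- c(a = 0.05 / 452, b = 1.43e-26, c = 0.2)
  cfg <- effector_config(n_celltypes_tested = 452)
  sig <- prioritize_celltypes(p, cfg)
  expect_false("a" %in% sig)    # boundary value is not significant
  expect_true("b" %in% sig)
  expect_length(prioritize_celltypes(setNames(numeric(0), character(0))), 0)
})

test_that("effector selection intersects specificity and rank gates", {
  spec <- matrix(c(0.99, 0.1,
                   0.98, 0.1,
                   0.10, 0.2), 3, 2, byrow = TRUE,
                 dimnames = list(c("hit", "ranked_out", "weak"),
                                 c("ct1", "ct2")))
  # add filler genes so the 95th percentile sits below the planted values
  filler <- matrix(runif(400, 0.01, 0.5), 200, 2,
                   dimnames = list(sprintf("f%03d", 1:200), c("ct1", "ct2")))
  spec <- rbind(spec, filler)
  ranks <- data.frame(gene = rownames(spec),
                      rank = c(500, 1500, 600, seq_len(200) + 2000))
  sel <- select_effector_genes(spec, ranks, effector_config())
  expect_equal(sel$gene, "hit")
  expect_equal(sel$best_celltype, "ct1")
  expect_error(select_effector_genes(spec, data.frame(gene = "zzz", rank = 1),
                                     effector_config()),
               "share no genes")
})

test_that("selection equals a brute-force per-gene check on random tables", {
  set.seed(12)
  for (i in 1:25) {
    n_genes <- sample(50:150, 1); n_ct <- sample(2:5, 1)
    spec <- matrix(runif(n_genes * n_ct), n_genes, n_ct,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("ct%d", 1:n_ct)))
    spec[sample(length(spec), round(0.3 * length(spec)))] <- 0
    ranks <- data.frame(gene = rownames(spec), rank = sample(n_genes))
    cfg <- effector_config(specificity_percentile = sample(c(80, 95), 1),
                           top_n_genes = sample(10:60, 1))
    sel <- select_effector_genes(spec, ranks, cfg)$gene
    # independent per-gene check
    cut <- apply(spec, 2, function(v)
      quantile(v[v > 0], cfg$specificity_percentile / 100, names = FALSE))
    manual <- rownames(spec)[sapply(seq_len(n_genes), function(g)
      any(spec[g, ] > cut) &&
        ranks$rank[ranks$gene == rownames(spec)[g]] <= cfg$top_n_genes)]
    expect_setequal(sel, manual)
  }
})

test_that("selection is monotone in the percentile and rank gates", {
  set.seed(13)
  spec <- matrix(runif(600), 200, 3,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("ct", 1:3)))
  ranks <- data.frame(gene = rownames(spec), rank = sample(200))
  base <- select_effector_genes(spec, ranks,
                                effector_config(specificity_percentile = 90,
                                                top_n_genes = 100))$gene
  tighter_pct <- select_effector_genes(
    spec, ranks, effector_config(specificity_percentile = 97,
                                 top_n_genes = 100))$gene
  tighter_rank <- select_effector_genes(
    spec, ranks, effector_config(specificity_percentile = 90,
                                 top_n_genes = 40))$gene
  expect_true(all(tighter_pct %in% base))
  expect_true(all(tighter_rank %in% base))
})

test_that("burden prioritization reproduces the published thresholds", {
  # 0.05/426 ~ 1.17e-4: p = 5.6e-6 passes, 2e-4 does not
  p <- c(CORO1A = 5.6e-6, other = 2e-4)
  sig <- prioritize_effector_burden(p, n_genes_tested = 426)
  expect_equal(sig, "CORO1A")
  # single test: plain alpha
  expect_equal(prioritize_effector_burden(c(g = 0.04), 1), "g")
  expect_length(prioritize_effector_burden(c(g = 0.06), 1), 0)
})
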
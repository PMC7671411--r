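test_that("rank_sum_markers finds planted up-regulated genes only", {
  set.seed(1)
  n <- 120; g <- 30
  X <- matrix(rexp(n * g, rate = 2), n, g)
  labels <- rep(1:2, each = 60)
  X[labels == 2, 5] <- X[labels == 2, 5] + 5     # planted marker, cluster 2
  m <- expression_matrix(X, layer = "lognorm")
  mk <- rank_sum_markers(m, labels, p_max = 1e-6, fc_min = 1.5)
  expect_true(any(mk$cluster == 2 & mk$gene == "gene_5"))
  expect_false(any(mk$gene != "gene_5"))          # null genes excluded
  expect_error(rank_sum_markers(m, rep(1, n)), "2 clusters")

  # invariance to cell reordering
  set.seed(2)
  ord <- sample(n)
  m2 <- expression_matrix(X[ord, ], layer = "lognorm")
  mk2 <- rank_sum_markers(m2, labels[ord], p_max = 1e-6, fc_min = 1.5)
  expect_equal(mk2[order(mk2$cluster, mk2$gene), c("p_value", "fold_change")],
               mk[order(mk$cluster, mk$gene), c("p_value", "fold_change")],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("small-sample p-values match the exact rank-sum oracle", {
  # 5 vs 5, all in-cluster values above all others: p = 1/choose(10,5)
  x <- c(6, 7, 8, 9, 10, 1, 2, 3, 4, 5) / 10
  labels <- rep(c("hi", "lo"), each = 5)
  m <- expression_matrix(matrix(x, ncol = 1), layer = "lognorm")
  mk <- rank_sum_markers(m, labels, p_max = 1, fc_min = 0.01)
  p_hi <- mk$p_value[mk$cluster == "hi"]
  expect_equal(p_hi, 1 / choose(10, 5), tolerance = 1e-12)
  # and agrees with stats::wilcox.test as an independent oracle
  or <- wilcox.test(x[1:5], x[6:10], alternative = "greater",
                    exact = TRUE)$p.value
  expect_equal(p_hi, or, tolerance = 1e-12)

  # recompute fold change from raw data
  eps <- 1e-9
  expect_equal(mk$fold_change[mk$cluster == "hi"],
               (mean(x[1:5]) + eps) / (mean(x[6:10]) + eps))
})

test_that("large-sample p-values track the normal-approximation oracle", {
  set.seed(3)
  x <- c(rnorm(40, 1.2), rnorm(80, 1))
  labels <- rep(1:2, c(40, 80))
  m <- expression_matrix(matrix(pmax(x, 0), ncol = 1), layer = "lognorm")
  mk <- rank_sum_markers(m, labels, p_max = 1, fc_min = 0.01)
  or <- wilcox.test(pmax(x[1:40], 0), pmax(x[41:120], 0),
                    alternative = "greater", correct = TRUE,
                    exact = FALSE)$p.value
  expect_equal(mk$p_value[mk$cluster == 1], or, tolerance = 1e-6)
})

test_that("enrichment p-value matches full-support brute force", {
  expect_equal(enrichment_pvalue(100, 10, 20, 0), 1)
  expect_equal(enrichment_pvalue(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:30) {
    N <- sample(10:60, 1)
    a <- sample(1:N, 1); b <- sample(1:N, 1)
    k <- sample(0:min(a, b), 1)
    expect_equal(enrichment_pvalue(N, a, b, k),
                 hyper_tail_bruteforce(N, a, b, k),
                 tolerance = 1e-12)
  }
  # strictly decreasing in k
  p <- sapply(0:8, function(k) enrichment_pvalue(50, 10, 8, k))
  expect_true(all(diff(p) < 0))
  expect_error(enrichment_pvalue(10, 5, 5, 6), "overlap")
  expect_error(enrichment_pvalue(10, 11, 5, 2), "background")
})

test_that("cell-type assignment ranks by enrichment with Jaccard tiebreak", {
  mk <- data.frame(cluster = c(1, 1, 1, 2),
                   gene = c("A", "B", "C", "Z"),
                   p_value = 1e-9, fold_change = 2)
  class(mk) <- c("marker_table", "data.frame")
  ref <- list(typeX = c("A", "B", "C"),       # exact match for cluster 1
              typeY = c("A", "Q", "R", "S"),
              typeZ = c("M", "N"))
  res <- assign_cell_types(mk, ref, n_bg = 50)
  a1 <- res$assignments[res$assignments$cluster == 1, ]
  expect_equal(a1$cell_type, "typeX")
  expect_equal(a1$jaccard, 1)
  expect_equal(a1$p_value, enrichment_pvalue(50, 3, 3, 3))
  # cluster 2 overlaps nothing -> unknown with p = 1
  a2 <- res$assignments[res$assignments$cluster == 2, ]
  expect_equal(a2$cell_type, "unknown")
  expect_equal(a2$p_value, 1)
  # all candidate scores retained
  expect_equal(nrow(res$scores), 2 * length(ref))
  # hand-computed ranking for partially overlapping types
  sc1 <- res$scores[res$scores$cluster == 1, ]
  expect_equal(sc1$overlap[sc1$cell_type == "typeY"], 1)
  expect_equal(sc1$jaccard[sc1$cell_type == "typeY"], 1 / 6)
  expect_lt(a1$p_value, sc1$p_value[sc1$cell_type == "typeY"])

  # reference reader round trip (case folding happens in assignment)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("cell_type\tgene", "typeX\ta", "typeX\tB", "typeW\tq"), path)
  ref2 <- read_marker_reference(path)
  expect_equal(sort(names(ref2)), c("typeW", "typeX"))
  res2 <- assign_cell_types(mk, ref2, n_bg = 50)
  expect_equal(res2$scores$overlap[res2$scores$cluster == 1 &
                                   res2$scores$cell_type == "typeX"], 2)
})

test_that("cluster trajectory reproduces the complete-linkage hand trace", {
  emb <- matrix(c(0, 0.1, 1, 1.1, 10, 10.2), ncol = 1)
  labels <- rep(1:3, each = 2)
  tr <- cluster_trajectory(emb, labels)
  expect_equal(dim(tr$dist), c(3L, 3L))
  expect_true(isSymmetric(tr$dist))
  expect_equal(diag(tr$dist), rep(0, 3), ignore_attr = TRUE)
  # means at 0.05, 1.05, 10.1: first merge {1,2} at 1, final at 10.05
  expect_equal(tr$tree$height, c(1, 10.05), tolerance = 1e-9)
  expect_equal(sort(tr$tree$merge[1, ]), c(-2, -1))
  # non-decreasing merge heights (ultrametric property)
  set.seed(5)
  emb2 <- matrix(rnorm(200), 100, 2)
  lab2 <- sample(6, 100, TRUE)
  tr2 <- cluster_trajectory(emb2, lab2)
  expect_true(all(diff(tr2$tree$height) >= -1e-12))
  expect_error(cluster_trajectory(emb2, rep(1, 100)), "2 clusters")

  # identical means merge at height zero
  emb3 <- rbind(c(1, 2), c(1, 2), c(5, 5), c(1, 2), c(1, 2), c(5, 5))
  tr3 <- cluster_trajectory(emb3[1:4, ], c(1, 1, 2, 3))
  expect_equal(min(tr3$tree$height), 0)

  # newick export is readable by ape
  path <- tempfile(fileext = ".nwk")
  write_trajectory_newick(tr2, path)
  tree <- ape::read.tree(path)
  expect_equal(sort(tree$tip.label), sort(rownames(tr2$means)))
})
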
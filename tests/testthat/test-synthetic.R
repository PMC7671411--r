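test_that("gaussian mixtures respect sizes, separation and recoverability", {
  set.seed(1)
  gm <- simulate_gaussian_mixture(10, 3, 5)
  expect_equal(dim(gm$points), c(10L, 3L))
  expect_equal(gm$labels, rep(1L, 10))

  set.seed(2)
  gm0 <- simulate_gaussian_mixture(c(30, 30), 4, 0)
  mu1 <- colMeans(gm0$points[gm0$labels == 1, ])
  mu2 <- colMeans(gm0$points[gm0$labels == 2, ])
  expect_lt(sqrt(sum((mu1 - mu2)^2)), 1)       # coincident clusters

  # nearest inter-mean distance equals the requested separation
  set.seed(3)
  gm3 <- simulate_gaussian_mixture(c(50, 50, 50, 50), 6, 7)
  centers <- rowsum(gm3$points, gm3$labels) / 50
  expect_equal(min(dist(centers)), 7, tolerance = 0.3)

  # (2000, 50) at separation 6: nearest-true-mean classification < 1% error
  set.seed(4)
  gm <- simulate_gaussian_mixture(c(2000, 50), 10, 6)
  mu <- rowsum(gm$points, gm$labels) / c(2000, 50)
  d1 <- colSums((t(gm$points) - mu[1, ])^2)
  d2 <- colSums((t(gm$points) - mu[2, ])^2)
  expect_lt(mean((1 + (d2 < d1)) != gm$labels), 0.01)
  expect_error(simulate_gaussian_mixture(c(5, 5), 0, 1), "d must")
})

test_that("count simulation is reproducible with integer counts and stated sizes", {
  spec <- sim_spec(n_cells = 200, n_genes = 150)
  set.seed(5); s1 <- simulate_counts(spec)
  set.seed(5); s2 <- simulate_counts(spec)
  expect_identical(as.matrix(s1$matrix$values), as.matrix(s2$matrix$values))
  expect_identical(s1$labels, s2$labels)
  v <- as.matrix(s1$matrix$values)
  expect_true(all(v == round(v)) && all(v >= 0))
  expect_equal(s1$matrix$layer, "raw")
  expect_equal(sum(s1$group_sizes), 200)

  # the default imbalanced proportions at the stated 5000-cell scale
  sizes <- cellsketch:::apportion(5000, sim_spec()$group_proportions)
  expect_equal(min(sizes), 75)      # smallest cluster: about 1.5%
  expect_equal(max(sizes), 1160)    # largest: roughly 23.2%
  expect_equal(sum(sizes), 5000)
  expect_error(sim_spec(group_proportions = c(0.5, 0.4)), "sum to 1")
})

test_that("logistic dropout behaves at the limits and monotonically", {
  set.seed(6)
  sim <- simulate_counts(sim_spec(n_cells = 150, n_genes = 200))
  m <- sim$matrix
  base_sparsity <- mean(as.matrix(m$values) == 0)

  # midpoint far below every log-mean: matrix unchanged
  set.seed(7)
  un <- add_dropout(m, midpoint = -40)
  expect_equal(as.matrix(un$values), as.matrix(m$values),
               ignore_attr = TRUE)
  # steep curve with midpoint above every log-mean: all zeros
  set.seed(8)
  all0 <- add_dropout(m, midpoint = 40, shape = 50)
  expect_true(all(as.matrix(all0$values) == 0))

  # realized sparsity is monotone over a midpoint sweep
  mids <- c(-2, -1, 0, 1, 2)
  sp <- sapply(mids, function(mp) {
    set.seed(9)
    mean(as.matrix(add_dropout(m, mp)$values) == 0)
  })
  expect_true(all(diff(sp) > 0))
  expect_true(all(sp >= base_sparsity))
})

test_that("dropout calibration hits target sparsities", {
  # a ~70%-sparse base raised to 85 / 90 / 96% within a point
  set.seed(10)
  sim <- simulate_counts(sim_spec(n_cells = 400, n_genes = 600,
                                  gamma_scale = 0.8))
  m <- sim$matrix
  expect_gt(sim$sparsity, 0.6); expect_lt(sim$sparsity, 0.8)
  for (target in c(0.85, 0.90, 0.96)) {
    mid <- calibrate_dropout_midpoint(m, target)
    set.seed(11)
    realized <- mean(as.matrix(add_dropout(m, mid)$values) == 0)
    expect_lt(abs(realized - target), 0.01)
  }
  expect_error(calibrate_dropout_midpoint(m, 0.1), "below current")
})

test_that("rare spike-in mixtures have the stated composition", {
  spec <- sim_spec(n_cells = 100, n_genes = 300)
  set.seed(12)
  mix <- spike_rare_mixture(1540, 40, spec, shift_strength = 1.5)
  expect_equal(sum(mix$rare_mask), 40)
  expect_equal(length(mix$rare_mask), 1580)
  expect_equal(mean(mix$rare_mask), 40 / 1580)

  # sweep of rare fractions produces masks of matching sizes
  for (frac in c(0.005, 0.01, 0.015, 0.02)) {
    n_rare <- round(1540 * frac / (1 - frac))
    set.seed(13)
    mx <- spike_rare_mixture(1540, n_rare,
                             sim_spec(n_cells = 100, n_genes = 120),
                             shift_strength = 1.5)
    expect_equal(sum(mx$rare_mask), n_rare)
  }
  expect_error(spike_rare_mixture(10, 0, spec), "n_rare")
  expect_error(spike_rare_mixture(5, 10, spec), "n_abundant")
})

test_that("a strong shift makes the rare population separable", {
  # fixture sanity: 2-means on 50 principal directions recovers the spike
  ok <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    mix <- spike_rare_mixture(760, 40, sim_spec(n_cells = 100, n_genes = 400),
                              shift_strength = 2)
    ml <- normalize_and_log(filter_min_count(mix$matrix))
    mask <- mix$rare_mask[match(ml$cell_ids, mix$matrix$cell_ids)]
    X <- as.matrix(ml$values)
    X <- sweep(X, 2, colMeans(X))
    pc <- X %*% svd(X, nu = 0, nv = 50)$v
    km <- kmeans(pc, 2, nstart = 5)
    ok <- ok + (rare_detection_f1(mask, km$cluster) == 1)
  }
  expect_gte(ok, 9)
})
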
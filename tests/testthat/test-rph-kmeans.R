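test_that("hash families have the stated distributions and arithmetic", {
  expect_error(sample_hash_family(3, 1, 0), "positive")
  set.seed(1); f1 <- sample_hash_family(4, 3, 2)
  set.seed(1); f2 <- sample_hash_family(4, 3, 2)
  expect_identical(f1, f2)
  expect_equal(dim(f1$a), c(3L, 4L))
  expect_true(all(f1$b >= 0 & f1$b < 2))

  # moment check on 1e5 entries
  set.seed(2)
  f <- sample_hash_family(1000, 100, 1)
  a <- as.vector(f$a)
  expect_lt(abs(mean(a)), 3 * 1 / sqrt(length(a)))
  expect_lt(abs(var(a) - 1), 3 * sqrt(2 / length(a)))

  # worked example: v=[1,0], a=[1,0], b=0.5, w=1 -> floor(1.5) = 1
  f <- structure(list(a = matrix(c(1, 0), 1), b = 0.5, w = 1, l = 1L),
                 class = "hash_family")
  expect_equal(as.vector(hash_point(f, c(1, 0))), 1)
  # identical points always share codes
  set.seed(3)
  f <- sample_hash_family(5, 4, 0.3)
  p <- rnorm(5)
  expect_identical(hash_point(f, p), hash_point(f, p))
  # enormous w puts everything in one bucket
  set.seed(4)
  f <- sample_hash_family(3, 2, 1e9)
  codes <- hash_point(f, matrix(rnorm(60), 20, 3))
  expect_equal(nrow(unique(codes)), 1L)
  expect_error(hash_point(f, c(1, 2)), "dimension")
})

test_that("collision probability decreases with distance (LSH contract)", {
  # small version of the acceptance check: 1500 families, l = 1, fixed w
  w <- 1
  set.seed(10)
  dists <- c(0.1, 0.5, 2) * w
  coll <- sapply(dists, function(dd) {
    hits <- 0
    for (i in 1:1500) {
      f <- sample_hash_family(2, 1, w)
      codes <- hash_point(f, rbind(c(0, 0), c(dd, 0)))
      hits <- hits + (codes[1] == codes[2])
    }
    hits / 1500
  })
  expect_true(all(diff(coll) < 0))
})

test_that("reduce_points_once merges buckets to weighted centroids", {
  set.seed(5)
  f <- sample_hash_family(2, 2, 0.5)
  # all points identical -> one output point with summed weight
  pts <- matrix(1.3, 5, 2)
  red <- reduce_points_once(pts, rep(2, 5), f)
  expect_equal(nrow(red$points), 1L)
  expect_equal(red$weights, 10)
  expect_equal(as.vector(red$points), c(1.3, 1.3))
  expect_equal(red$map, rep(1L, 5))

  # two coincident weighted points plus a far singleton
  pts <- rbind(c(0, 0), c(0, 0), c(50, 50))
  red <- reduce_points_once(pts, c(1, 3, 1), sample_hash_family(2, 2, 0.5))
  expect_equal(sum(red$weights), 5)
  merged <- which(red$weights == 4)
  expect_equal(as.vector(red$points[merged, ]), c(0, 0))

  # no collisions: output = input up to ordering
  set.seed(6)
  pts <- matrix(rnorm(20, sd = 100), 10, 2)
  f <- sample_hash_family(2, 3, 1e-4)
  red <- reduce_points_once(pts, rep(1, 10), f)
  expect_equal(nrow(red$points), 10L)
  expect_equal(sort(red$points[, 1]), sort(pts[, 1]), ignore_attr = TRUE)
})

test_that("radius splitting follows the sequential founder rule", {
  # hand trace: 1-D points 0, 0.4, 5 with r = 1 -> {0, 0.4} and {5}
  assign <- split_bucket_radius(matrix(c(0, 0.4, 5), 3, 1), 1)
  expect_equal(assign, c(1L, 1L, 2L))
  # all points within r of the first -> one sub-bucket
  expect_equal(split_bucket_radius(matrix(c(0, 0.5, -0.5), 3, 1), 1),
               rep(1L, 3))
  # two distant points -> two sub-buckets
  expect_equal(split_bucket_radius(matrix(c(0, 10), 2, 1), 1), c(1L, 2L))
  expect_error(split_bucket_radius(matrix(0), -1), "positive")
})

test_that("size filtering partitions buckets by summed weight", {
  expect_equal(filter_buckets_size(c(1, 1, 1), 1), rep(TRUE, 3))
  expect_equal(filter_buckets_size(c(10), 5), FALSE)
  set.seed(7)
  bw <- sample(1:20, 12, replace = TRUE)
  expect_equal(filter_buckets_size(bw, 7), bw <= 7)
})

test_that("build_skeleton conserves weight and respects the target", {
  set.seed(8)
  pts <- matrix(rnorm(40), 20, 2)
  sk <- build_skeleton(pts, rph_config(), skeleton_target = 100)
  expect_identical(sk$points, pts)            # identity case: N <= target
  expect_equal(sk$weights, rep(1, 20))

  same <- matrix(2, 30, 3)
  sk <- build_skeleton(same, rph_config(), skeleton_target = 5)
  expect_equal(nrow(sk$points), 1L)
  expect_equal(sk$weights, 30)
  expect_equal(sk$iterations, 1L)

  # weight conservation + provenance across a real reduction
  set.seed(9)
  pts <- matrix(rnorm(600), 300, 2)
  sk <- build_skeleton(pts, rph_config(), skeleton_target = 30)
  expect_identical(sum(sk$weights), 300)
  expect_equal(length(sk$provenance), 300)
  expect_true(all(sk$provenance %in% seq_len(nrow(sk$points))))
  expect_equal(as.vector(table(sk$provenance)[as.character(seq_along(sk$weights))]),
               as.vector(sk$weights), ignore_attr = TRUE)
  expect_error(build_skeleton(pts, rph_config(), skeleton_target = 0),
               "skeleton_target")
})

test_that("weighted k-means++ seeding follows the weight law", {
  # first-pick frequencies proportional to weights (classic rule, 1 trial)
  pts <- matrix(c(0, 10, 20), 3, 1)
  w <- c(1, 2, 7)
  picks <- integer(3)
  set.seed(12)
  for (i in 1:4000) {
    ctr <- weighted_kmeanspp_init(pts, w, 1, n_trials = 1)
    picks[which(pts == ctr[1, 1])] <- picks[which(pts == ctr[1, 1])] + 1
  }
  freq <- picks / 4000
  p <- w / 10
  expect_true(all(abs(freq - p) < 3.5 * sqrt(p * (1 - p) / 4000)))

  # k = number of distinct points -> centers are exactly those points
  set.seed(13)
  pts <- matrix(c(0, 5, 11), 3, 1)
  ctr <- weighted_kmeanspp_init(pts, rep(1, 3), 3)
  expect_equal(sort(ctr[, 1]), c(0, 5, 11))
  expect_error(weighted_kmeanspp_init(pts, rep(1, 3), 4), "fewer points")
})

test_that("weighted Lloyd matches the unweighted algorithm and examples", {
  set.seed(14)
  pts <- matrix(rnorm(100), 50, 2)
  init <- pts[c(3, 27), ]
  a <- weighted_kmeans(pts, rep(1, 50), 2, init)
  b <- weighted_kmeans(pts, rep(4, 50), 2, init)  # equal weights = same labels
  expect_identical(a$labels, b$labels)
  expect_equal(b$inertia, 4 * a$inertia, tolerance = 1e-9)

  # k = 1 converges to the weighted mean
  wts <- runif(50, 1, 3)
  one <- weighted_kmeans(pts, wts, 1, pts[1, , drop = FALSE])
  expect_equal(as.vector(one$centers),
               as.vector(colSums(pts * wts) / sum(wts)), tolerance = 1e-6)

  # two 1-D points at 0 and 1, weights (9, 1), k = 1 -> center 0.1
  fit <- weighted_kmeans(matrix(c(0, 1), 2, 1), c(9, 1), 1,
                         matrix(0.5, 1, 1))
  expect_equal(as.vector(fit$centers), 0.1)
  expect_equal(fit$inertia, 9 * 0.01 + 1 * 0.81)

  # inertia from converged fit never exceeds inertia at the init
  set.seed(15)
  pts <- matrix(rnorm(200), 100, 2)
  init <- pts[sample(100, 3), ]
  d2 <- sapply(1:3, function(c_) colSums((t(pts) - init[c_, ])^2))
  inertia0 <- sum(apply(d2, 1, min))
  fit <- weighted_kmeans(pts, NULL, 3, init)
  expect_lte(fit$inertia, inertia0 + 1e-9)
})

test_that("rph_kmeans solves exact and degenerate cases deterministically", {
  pts <- matrix(c(0, 0, 10, 10, -10, 5), 3, 2, byrow = TRUE)
  set.seed(16)
  fit <- rph_kmeans(pts, 3)
  expect_equal(sort(unique(fit$labels)), 1:3)
  expect_equal(fit$inertia, 0)

  set.seed(17)
  gm <- simulate_gaussian_mixture(c(60, 40), 4, 9)
  set.seed(18); f1 <- rph_kmeans(gm$points, 2)
  set.seed(18); f2 <- rph_kmeans(gm$points, 2)
  expect_identical(f1$labels, f2$labels)
  expect_error(rph_kmeans(pts, 4), "fewer points")
})

test_that("weighted BIC recovers k on a clear fixture", {
  set.seed(19)
  gm <- simulate_gaussian_mixture(c(80, 80, 80), 4, 10)
  sk <- list(points = gm$points, weights = rep(1, 240))
  est <- estimate_k_weighted_bic(sk, 2:6)
  expect_equal(est$k, 3L)
  expect_equal(nrow(est$scores), 5L)
  # singleton range is trivially the answer
  expect_equal(estimate_k_weighted_bic(sk, 3)$k, 3L)
  expect_error(estimate_k_weighted_bic(sk, integer(0)), "empty")
})
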
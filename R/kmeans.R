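# squared Euclidean distances, points (n x d) vs centers (k x d) -> n x k
dist2_mat <- function(points, centers) {
  n2p <- rowSums(points^2)
  n2c <- rowSums(centers^2)
  d2 <- outer(n2p, n2c, "+") - 2 * points %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

#' Weighted k-means++ seeding
#'
#' The first center is drawn with probability proportional to weight; each
#' subsequent center with probability proportional to weight times squared
#' distance to the nearest already-chosen center. As in the standard
#' greedy k-means++ variant, `n_trials` candidates are sampled from that
#' distribution at every step and the one minimizing the resulting
#' weighted potential is kept (`n_trials = 1` recovers the classic rule).
#'
#' @param points n x d matrix.
#' @param weights length-n positive weights (default all 1).
#' @param k number of centers (<= n).
#' @param n_trials candidate draws per center (greedy selection).
#' @return k x d matrix of initial centers.
#' @export
weighted_kmeanspp_init <- function(points, weights = NULL, k, n_trials = 8L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  if (n < k) stop("fewer points (", n, ") than centers (", k, ")")
  centers <- matrix(0, k, ncol(points))
  first <- sample.int(n, 1, prob = weights)
  centers[1, ] <- points[first, ]
  if (k > 1) {
    d2 <- dist2_mat(points, centers[1, , drop = FALSE])[, 1]
    for (c_idx in 2:k) {
      p <- weights * d2
      if (sum(p) > 0) {
        cand <- sample.int(n, n_trials, replace = TRUE, prob = p)
        pots <- vapply(cand, function(ix) {
          dc <- dist2_mat(points, points[ix, , drop = FALSE])[, 1]
          sum(weights * pmin(d2, dc))
        }, numeric(1))
        idx <- cand[which.min(pots)]
      } else idx <- which.max(d2)      # all mass zero: any farthest point
      centers[c_idx, ] <- points[idx, ]
      d2 <- pmin(d2, dist2_mat(points, centers[c_idx, , drop = FALSE])[, 1])
    }
  }
  centers
}

#' Weighted Lloyd's k-means
#'
#' Alternates nearest-center assignment (ties broken toward the lowest
#' center index) and weight-scaled centroid updates until the largest
#' center shift drops below `tol` or `max_iters` is hit. An emptied
#' cluster is re-seeded at the point with the largest weighted squared
#' distance to its current center.
#'
#' @param points n x d matrix.
#' @param weights length-n positive weights (default all 1, in which case
#'   this is standard Lloyd).
#' @param k number of clusters.
#' @param init_centers k x d matrix of starting centers; `NULL` uses
#'   [weighted_kmeanspp_init()].
#' @param max_iters,tol iteration cap and center-shift tolerance.
#' @return a `cluster_result`: `labels` (1..k), `centers`, `inertia`
#'   (weighted within-cluster sum of squares), `k`, `iterations`,
#'   `converged`, `reseeded` (count of empty-cluster repairs).
#' @export
weighted_kmeans <- function(points, weights = NULL, k, init_centers = NULL,
                            max_iters = 300L, tol = 1e-4) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive, one per point")
  if (n < k) stop("fewer points (", n, ") than clusters (", k, ")")
  centers <- if (is.null(init_centers)) weighted_kmeanspp_init(points, weights, k)
  else as.matrix(init_centers)
  if (nrow(centers) != k) stop("init_centers must have k rows")

  labels <- integer(n)
  reseeded <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    d2 <- dist2_mat(points, centers)
    labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters before the update
    for (c_idx in which(tabulate(labels, k) == 0L)) {
      far <- which.max(weights * d2[cbind(seq_len(n), labels)])
      labels[far] <- c_idx
      reseeded <- reseeded + 1L
    }
    wsum <- as.numeric(rowsum(weights, labels))
    new_centers <- rowsum(points * weights, labels) / wsum
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- dist2_mat(points, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(weights * d2[cbind(seq_len(n), labels)])
  structure(list(labels = labels, centers = centers, inertia = inertia,
                 k = k, iterations = iter, converged = converged,
                 reseeded = reseeded),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, n = %d, inertia = %.4g (%d iterations%s)\n",
              x$k, length(x$labels), x$inertia, x$iterations,
              if (x$converged) ", converged" else ""))
  print(table(cluster = x$labels))
  invisible(x)
}

#' k-means++ initialized Lloyd on raw points (baseline)
#'
#' The conventional single-initialization baseline RPH-kmeans is compared
#' against: k-means++ seeding directly on the full data, then Lloyd.
#'
#' @inheritParams weighted_kmeans
#' @return a `cluster_result`.
#' @export
kmeanspp <- function(points, k, max_iters = 300L, tol = 1e-4,
                     n_trials = 8L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  init <- weighted_kmeanspp_init(points, NULL, k, n_trials = n_trials)
  weighted_kmeans(points, NULL, k, init_centers = init,
                  max_iters = max_iters, tol = tol)
}

#' RPH-kmeans: skeleton-initialized k-means
#'
#' Builds a weighted data skeleton by iterative locality-sensitive
#' hashing, fits weighted k-means (k-means++ seeded) on the skeleton, then
#' runs standard Lloyd on the full data from the skeleton-derived centers.
#' Because the skeleton collapses dense regions far more than sparse ones,
#' the initial centers are not biased toward large populations, which is
#' what lets small clusters survive.
#'
#' @param points N x d numeric matrix (typically an embedding).
#' @param k number of clusters (<= N).
#' @param cfg an [rph_config()].
#' @return a `cluster_result` for the full data, with the skeleton of the
#'   winning restart attached as attribute `"skeleton"`.
#' @export
rph_kmeans <- function(points, k, cfg = rph_config()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < k) stop("fewer points (", n, ") than clusters (", k, ")")
  target <- cfg$skeleton_target %||% max(8L, 4L * k)
  best <- NULL
  for (rep_i in seq_len(max(1L, cfg$n_init))) {
    sk <- build_skeleton(points, cfg, skeleton_target = max(target, k))
    # guard: reduction below k points (tiny data) -> fall back to raw points
    if (nrow(sk$points) < k)
      sk <- list(points = points, weights = rep(1, n))
    init <- weighted_kmeanspp_init(sk$points, sk$weights, k,
                                   n_trials = cfg$kpp_trials)
    skfit <- weighted_kmeans(sk$points, sk$weights, k, init_centers = init,
                             max_iters = cfg$max_lloyd_iters, tol = cfg$tol)
    fit <- weighted_kmeans(points, NULL, k, init_centers = skfit$centers,
                           max_iters = cfg$max_lloyd_iters, tol = cfg$tol)
    if (is.null(best) || fit$inertia < best$inertia) {
      best <- fit
      attr(best, "skeleton") <- sk
    }
  }
  best
}
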
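#' Estimate the number of clusters by weighted BIC on a skeleton
#'
#' For each candidate `k`, weighted k-means is fitted to the skeleton and
#' scored by a weighted spherical-Gaussian BIC: each cluster contributes a
#' hard-assignment Gaussian log-likelihood with its own scalar variance,
#' every skeleton point's log-density multiplied by its weight, minus the
#' penalty `0.5 * p_k * ln(W)` with `p_k = k*d + k + (k-1)` free
#' parameters (centers, variances, mixing proportions) and `W` the total
#' weight. The candidate maximizing the score wins.
#'
#' @param skeleton a `skeleton` from [build_skeleton()], or any list with
#'   `points` and `weights`.
#' @param k_range integer vector of candidate cluster counts.
#' @param n_init restarts of weighted k-means per candidate.
#' @param max_iters,tol Lloyd controls.
#' @return list with `k` (the argmax), `scores` (data.frame of k, BIC,
#'   inertia) and `fits` (the winning `cluster_result` per candidate).
#' @export
estimate_k_weighted_bic <- function(skeleton, k_range, n_init = 3L,
                                    max_iters = 100L, tol = 1e-4) {
  pts <- as.matrix(skeleton$points)
  wts <- skeleton$weights
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k_range")
  if (max(k_range) > nrow(pts))
    stop("max(k_range) exceeds skeleton size (", nrow(pts), ")")
  scores <- numeric(length(k_range))
  inertias <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (idx in seq_along(k_range)) {
    k <- k_range[idx]
    best <- NULL
    for (r in seq_len(max(1L, n_init))) {
      fit <- weighted_kmeans(pts, wts, k,
                             init_centers = weighted_kmeanspp_init(pts, wts, k),
                             max_iters = max_iters, tol = tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    scores[idx] <- weighted_bic_score(pts, wts, best)
    inertias[idx] <- best$inertia
    fits[[idx]] <- best
  }
  list(k = k_range[which.max(scores)],
       scores = data.frame(k = k_range, bic = scores, inertia = inertias),
       fits = fits)
}

# weighted spherical-Gaussian BIC score (larger is better)
weighted_bic_score <- function(points, weights, fit) {
  d <- ncol(points)
  W <- sum(weights)
  k <- fit$k
  ll <- 0
  for (c_idx in seq_len(k)) {
    in_c <- fit$labels == c_idx
    if (!any(in_c)) next
    w_c <- weights[in_c]
    W_c <- sum(w_c)
    dev <- sweep(points[in_c, , drop = FALSE], 2, fit$centers[c_idx, ])
    ss <- sum(w_c * rowSums(dev^2))
    sigma2 <- max(ss / (W_c * d), 1e-12)
    ll <- ll + W_c * log(W_c / W) -
      W_c * (d / 2) * log(2 * pi * sigma2) -
      ss / (2 * sigma2)
  }
  p_k <- k * d + k + (k - 1)
  ll - 0.5 * p_k * log(W)
}
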
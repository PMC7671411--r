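#' Configuration for RPH-kmeans
#'
#' @param l number of hash functions in the composite code (default 6):
#'   a bucket is the intersection of `l` random slabs, so distant points
#'   practically never collide while nearby ones still merge over the
#'   iterations.
#' @param w_scale multiplier on the adaptive quantization step: at each
#'   reduction iteration `w = w_scale * sd` of a one-dimensional random
#'   projection of (a subsample of) the current points.
#' @param skeleton_target stop reducing once at most this many weighted
#'   points remain. `NULL` defers to `max(8, 4k)` at clustering time
#'   (near-complete collapse, which is what de-biases the k-means++
#'   seeding) and to `max(2000, 20k)` when estimating k (a gentle
#'   reduction that preserves cluster variances for the BIC).
#' @param max_reduce_iters cap on LSH reduction iterations.
#' @param correction bucket correction applied before merging: `"radius"`
#'   (default: split buckets whose members stray beyond a radius, so a
#'   merge never fuses regions further apart than ~2 radii), `"size"`
#'   (merge only small buckets, pass large ones through) or `"none"`.
#' @param radius radius for `"radius"` correction; `NULL` = the current
#'   iteration's `w`.
#' @param size_threshold summed-weight threshold for `"size"` correction;
#'   `NULL` = the 95th percentile of bucket weights each iteration.
#' @param n_init number of full restarts; best final inertia wins.
#' @param kpp_trials greedy candidate draws in the k-means++ seeding.
#' @param max_lloyd_iters,tol Lloyd iteration cap and center-shift
#'   convergence tolerance.
#' @return an `rph_config` list.
#' @export
rph_config <- function(l = 6L, w_scale = 1.0, skeleton_target = NULL,
                       max_reduce_iters = 100L,
                       correction = c("radius", "size", "none"),
                       radius = NULL, size_threshold = NULL,
                       n_init = 1L, kpp_trials = 8L,
                       max_lloyd_iters = 300L, tol = 1e-4) {
  correction <- match.arg(correction)
  if (w_scale <= 0) stop("w_scale must be positive")
  if (l < 1) stop("l must be >= 1")
  structure(as.list(environment()), class = "rph_config")
}

#' Sample a random-projection hash family
#'
#' The p-stable LSH family for Euclidean distance:
#' `h_{a,b}(v) = floor((a . v + b) / w)` with `a` i.i.d. standard normal
#' and `b ~ U(0, w)`. A composite code concatenates `l` such functions;
#' two points collide iff all `l` components agree.
#'
#' @param d point dimension.
#' @param l number of hash functions.
#' @param w quantization step (> 0); larger `w` makes collisions more
#'   likely at a given distance.
#' @return a `hash_family` list with fields `a` (l x d), `b` (length l),
#'   `w`, `l`.
#' @export
sample_hash_family <- function(d, l = 1L, w = 1.0) {
  if (d < 1 || l < 1) stop("d and l must be >= 1")
  if (w <= 0) stop("quantization step w must be positive")
  structure(list(a = matrix(stats::rnorm(l * d), l, d),
                 b = stats::runif(l, 0, w), w = w, l = l),
            class = "hash_family")
}

#' Hash points to integer code vectors
#'
#' @param f a `hash_family`.
#' @param points numeric vector (one point) or N x d matrix.
#' @return integer code matrix, N x l.
#' @export
hash_point <- function(f, points) {
  stopifnot(inherits(f, "hash_family"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (ncol(points) != ncol(f$a))
    stop("points have dimension ", ncol(points),
         " but hash family expects ", ncol(f$a))
  proj <- points %*% t(f$a)          # N x l
  floor(sweep(proj, 2, f$b, "+") / f$w)
}

#' Split one bucket into sub-buckets by a greedy radius rule
#'
#' Points are scanned in their given order; each joins the nearest
#' already-founded sub-center if within `r`, otherwise founds a new
#' sub-bucket centered at itself. Order-dependent by construction.
#'
#' @param points n x d matrix of bucket members.
#' @param r positive radius.
#' @return integer vector of sub-bucket indices (1-based) per point.
#' @export
split_bucket_radius <- function(points, r) {
  if (r <= 0) stop("radius must be positive")
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  assign <- integer(n)
  centers <- matrix(0, 0, ncol(points))
  for (i in seq_len(n)) {
    if (nrow(centers) == 0L) {
      centers <- points[i, , drop = FALSE]
      assign[i] <- 1L
      next
    }
    d2 <- colSums((t(centers) - points[i, ])^2)
    nearest <- which.min(d2)
    if (sqrt(d2[nearest]) <= r) assign[i] <- nearest
    else {
      centers <- rbind(centers, points[i, ])
      assign[i] <- nrow(centers)
    }
  }
  assign
}

#' Partition buckets by summed weight
#'
#' Buckets whose summed weight is at most `size_threshold` are marked for
#' merging; members of heavier buckets pass through to the next iteration
#' as individual points (large buckets risk fusing distinct groups).
#'
#' @param bucket_weights numeric vector of per-bucket summed weights.
#' @param size_threshold positive threshold on summed weight.
#' @return logical vector: `TRUE` = merge this bucket.
#' @export
filter_buckets_size <- function(bucket_weights, size_threshold) {
  if (size_threshold < 1) stop("size_threshold must be >= 1")
  bucket_weights <= size_threshold
}

#' One LSH reduction pass
#'
#' Hashes every point with `f`, applies the configured bucket correction,
#' and merges each (sub-)bucket to its weighted centroid carrying the
#' summed weight. Total weight is conserved exactly.
#'
#' @param points N x d matrix.
#' @param weights length-N positive weights.
#' @param f a `hash_family`.
#' @param correction `"none"`, `"radius"` or `"size"`.
#' @param radius radius for `"radius"` correction (default: `f$w`).
#' @param size_threshold threshold for `"size"` correction (default: 95th
#'   percentile of bucket summed weights).
#' @return list with `points`, `weights`, and `map` (input index ->
#'   output row).
#' @export
reduce_points_once <- function(points, weights, f,
                               correction = c("none", "radius", "size"),
                               radius = NULL, size_threshold = NULL) {
  correction <- match.arg(correction)
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  if (length(weights) != nrow(points)) stop("weights/points length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  codes <- hash_point(f, points)
  key <- do.call(paste, c(lapply(seq_len(ncol(codes)), function(j) codes[, j]),
                          sep = "_"))
  group <- match(key, unique(key))

  if (correction == "radius") {
    r <- if (is.null(radius)) f$w else radius
    sub <- integer(length(group))
    for (g in unique(group)) {
      rows <- which(group == g)
      sub[rows] <- split_bucket_radius(points[rows, , drop = FALSE], r)
    }
    key2 <- paste(group, sub, sep = ".")
    group <- match(key2, unique(key2))
  } else if (correction == "size") {
    bw <- rowsum(weights, group)
    thr <- if (is.null(size_threshold))
      stats::quantile(bw, 0.95, names = FALSE) else size_threshold
    merge_ok <- filter_buckets_size(as.numeric(bw), max(thr, 1))
    # heavy-bucket members keep singleton groups (pass through unmerged)
    heavy <- !merge_ok[group]
    key2 <- ifelse(heavy, paste0("pt", seq_along(group)),
                   paste0("bk", group))
    group <- match(key2, unique(key2))
  }

  wsum <- as.numeric(rowsum(weights, group))
  ctr <- rowsum(points * weights, group) / wsum
  ord <- sort(unique(group))          # rowsum orders by group value
  map <- match(group, ord)
  list(points = ctr, weights = wsum, map = map)
}

#' Build a weighted data skeleton by iterative LSH reduction
#'
#' Repeatedly samples a fresh hash family (with an adaptive quantization
#' step: `w_scale` times the standard deviation of a random 1-D projection
#' of at most 1000 subsampled points) and merges colliding points, until at
#' most `skeleton_target` weighted points remain or `max_reduce_iters` is
#' reached. Weights always sum to the original point count.
#'
#' @param points N x d numeric matrix.
#' @param cfg an [rph_config()].
#' @param skeleton_target overrides `cfg$skeleton_target` when given.
#' @return a `skeleton`: list with `points` (S x d), `weights` (length S,
#'   summing to N), `provenance` (original index -> skeleton row),
#'   `iterations`.
#' @export
build_skeleton <- function(points, cfg = rph_config(),
                           skeleton_target = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 1) stop("no points")
  target <- skeleton_target %||% cfg$skeleton_target %||% 500L
  if (target < 1) stop("skeleton_target must be >= 1")

  pts <- points
  wts <- rep(1, n)
  prov <- seq_len(n)
  iters <- 0L
  while (nrow(pts) > target && iters < cfg$max_reduce_iters) {
    iters <- iters + 1L
    sub <- if (nrow(pts) > 1000)
      pts[sample.int(nrow(pts), 1000), , drop = FALSE] else pts
    dirv <- stats::rnorm(ncol(pts))
    s <- stats::sd(sub %*% dirv)
    w <- cfg$w_scale * if (is.finite(s) && s > 0) s else 1
    f <- sample_hash_family(ncol(pts), cfg$l, w)
    red <- reduce_points_once(pts, wts, f, cfg$correction,
                              radius = cfg$radius,
                              size_threshold = cfg$size_threshold)
    pts <- red$points
    wts <- red$weights
    prov <- red$map[prov]
  }
  structure(list(points = pts, weights = wts, provenance = prov,
                 iterations = iters),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d weighted points (total weight %g) after %d iterations\n",
              nrow(x$points), sum(x$weights), x$iterations))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
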
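#' Per-cluster marker genes by one-sided rank-sum test
#'
#' For every (cluster, gene) pair, tests whether the gene is up-regulated
#' inside the cluster relative to all remaining cells with a one-sided
#' Wilcoxon rank-sum test, and computes the fold change as the ratio of
#' group mean expressions (with a small pseudocount). A gene is reported
#' as a marker when `p <= p_max` and `fold change >= fc_min`.
#'
#' The test uses the normal approximation with tie and continuity
#' correction; when both group sizes are below 20 and the gene has no tied
#' values, the exact null distribution is used instead.
#'
#' @param m an `ExpressionMatrix` with `layer = "lognorm"`.
#' @param labels cluster labels, one per cell (>= 2 clusters).
#' @param p_max p-value cutoff (default `1e-6`; pick a small value near 0
#'   for a strict marker list).
#' @param fc_min fold-change cutoff (default 1.5).
#' @param eps pseudocount protecting the fold-change ratio.
#' @param adjust apply Benjamini-Hochberg correction per cluster before
#'   thresholding (off by default).
#' @return a `marker_table` data.frame with columns `cluster`, `gene`,
#'   `p_value`, `fold_change`, sorted by cluster then p-value; thresholds
#'   kept in attributes.
#' @export
rank_sum_markers <- function(m, labels, p_max = 1e-6, fc_min = 1.5,
                             eps = 1e-9, adjust = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("rank_sum_markers expects the lognorm layer")
  X <- em_dense(m)
  labels <- as.vector(labels)
  if (length(labels) != nrow(X)) stop("one label per cell required")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters to call markers")
  n <- nrow(X); G <- ncol(X)

  # per-gene ranks and tie corrections, shared across clusters
  ranks <- apply(X, 2, rank)
  tie_term <- apply(X, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  has_ties <- tie_term > 0

  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    in_c <- labels == clusters[ci]
    n1 <- sum(in_c); n2 <- n - n1
    if (n1 == 0) stop("empty cluster: ", clusters[ci])
    r1 <- colSums(ranks[in_c, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (u - mu - 0.5) / sqrt(pmax(sigma2, 1e-300))
    p <- stats::pnorm(z, lower.tail = FALSE)
    if (n1 < 20 && n2 < 20) {
      exact_ok <- which(!has_ties)
      if (length(exact_ok))
        p[exact_ok] <- stats::pwilcox(u[exact_ok] - 1, n1, n2,
                                      lower.tail = FALSE)
    }
    mean_in <- colMeans(X[in_c, , drop = FALSE])
    mean_out <- colMeans(X[!in_c, , drop = FALSE])
    fc <- (mean_in + eps) / (mean_out + eps)
    if (adjust) p <- stats::p.adjust(p, method = "BH")
    keep <- p <= p_max & fc >= fc_min
    if (any(keep))
      out[[ci]] <- data.frame(cluster = clusters[ci],
                              gene = m$gene_ids[keep],
                              p_value = p[keep],
                              fold_change = fc[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster = clusters[0], gene = character(0),
                      p_value = numeric(0), fold_change = numeric(0))
  res <- res[order(res$cluster, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p_max") <- p_max
  attr(res, "fc_min") <- fc_min
  attr(res, "adjusted") <- adjust
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing at least `k` genes in common
#' between a cluster's `a` markers and a reference set of `b` genes drawn
#' from `n_bg` background genes:
#' `p = sum_{i=k}^{min(a,b)} C(a,i) C(n_bg-a, b-i) / C(n_bg, b)`.
#' Evaluated in log space via the hypergeometric CDF, so it is stable for
#' genome-scale backgrounds.
#'
#' @param n_bg background gene count.
#' @param a cluster marker count.
#' @param b reference set size.
#' @param k overlap count (`0 <= k <= min(a, b)`).
#' @return a scalar in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
enrichment_pvalue <- function(n_bg, a, b, k) {
  if (a > n_bg || b > n_bg) stop("marker sets cannot exceed the background")
  if (k < 0 || k > min(a, b)) stop("overlap k must be in [0, min(a, b)]")
  if (k == 0) return(1)
  stats::phyper(k - 1, a, n_bg - a, b, lower.tail = FALSE)
}

#' Assign cell types to clusters by marker-set overlap
#'
#' Scores every (cluster, reference cell type) pair by overlap count,
#' matching rate `k/b` (fraction of the reference set recovered), Jaccard
#' index `k/(a+b-k)` and the hypergeometric [enrichment_pvalue()]. The
#' best type per cluster is the one with the smallest p-value (ties broken
#' by larger Jaccard); clusters with no markers or no overlap with any
#' type are labelled `"unknown"` with p = 1. Gene symbols are case-folded
#' before matching.
#'
#' @param markers a `marker_table` from [rank_sum_markers()].
#' @param reference named list of character gene sets (one per cell type),
#'   or a two-column data.frame `(cell_type, gene)`.
#' @param n_bg background gene count (typically the number of genes that
#'   survived filtering).
#' @return list with `assignments` (one row per cluster) and `scores`
#'   (every cluster x type candidate), both data.frames.
#' @export
assign_cell_types <- function(markers, reference, n_bg) {
  if (is.data.frame(reference))
    reference <- split(as.character(reference[[2]]),
                       as.character(reference[[1]]))
  if (!length(reference)) stop("empty reference marker list")
  reference <- lapply(reference, function(g) unique(toupper(g)))
  clusters <- unique(markers$cluster)
  scores <- list()
  assignments <- list()
  for (cl in clusters) {
    genes <- unique(toupper(markers$gene[markers$cluster == cl]))
    a <- length(genes)
    sc <- data.frame(cluster = cl, cell_type = names(reference),
                     overlap = NA_real_, cluster_markers = a,
                     reference_markers = NA_real_,
                     matching_rate = NA_real_, jaccard = NA_real_,
                     p_value = NA_real_)
    for (ti in seq_along(reference)) {
      b <- length(reference[[ti]])
      k <- length(intersect(genes, reference[[ti]]))
      sc$overlap[ti] <- k
      sc$reference_markers[ti] <- b
      sc$matching_rate[ti] <- if (b > 0) k / b else 0
      sc$jaccard[ti] <- if (a + b - k > 0) k / (a + b - k) else 0
      sc$p_value[ti] <- if (a == 0) 1 else enrichment_pvalue(n_bg, a, b, k)
    }
    scores[[length(scores) + 1L]] <- sc
    best <- order(sc$p_value, -sc$jaccard)[1]
    asg <- sc[best, , drop = FALSE]
    if (a == 0 || asg$overlap == 0) {
      asg$cell_type <- "unknown"
      asg$p_value <- 1
    }
    assignments[[length(assignments) + 1L]] <- asg
  }
  scores <- do.call(rbind, scores)
  assignments <- do.call(rbind, assignments)
  rownames(scores) <- rownames(assignments) <- NULL
  list(assignments = assignments, scores = scores)
}

#' Read a two-column cell-type marker reference
#' @param path delimited file with columns `(cell_type, gene)`, one gene
#'   per row, with or without a header.
#' @return named list of gene sets.
#' @export
read_marker_reference <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2) stop("reference needs two columns (cell_type, gene)")
  split(as.character(dt[[2]]), as.character(dt[[1]]))
}

#' Cluster-level trajectory structure
#'
#' Summarizes each cluster by its mean embedding vector, computes the
#' k x k Euclidean distance matrix between cluster means, and organizes
#' the clusters with complete-linkage hierarchical clustering. Clusters
#' from a common lineage sit close in embedding space, so the dendrogram
#' sketches a putative development hierarchy.
#'
#' @param embedding N x d numeric matrix.
#' @param labels cluster labels, one per row (>= 2 clusters).
#' @return a `trajectory_result`: `means` (k x d), `dist` (k x k matrix),
#'   `tree` (an `hclust`).
#' @export
cluster_trajectory <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.vector(labels)
  if (length(labels) != nrow(embedding)) stop("one label per row required")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  counts <- vapply(clusters, function(cl) sum(labels == cl), numeric(1))
  means <- rowsum(embedding, labels) / counts   # rowsum rows follow sort(unique(labels))
  rownames(means) <- as.character(clusters)
  dm <- as.matrix(stats::dist(means))
  tree <- stats::hclust(stats::as.dist(dm), method = "complete")
  structure(list(means = means, dist = dm, tree = tree),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory_result over %d clusters; merge heights %.3g .. %.3g\n",
              nrow(x$means), min(x$tree$height), max(x$tree$height)))
  invisible(x)
}

#' Plot a trajectory dendrogram (and optionally the distance heatmap)
#' @param x a `trajectory_result`.
#' @param heatmap also draw the cluster-distance heatmap.
#' @param ... passed to `plot.hclust`.
#' @export
plot.trajectory_result <- function(x, heatmap = FALSE, ...) {
  plot(x$tree, main = "cluster trajectory (complete linkage)",
       xlab = "cluster", sub = "", ...)
  if (heatmap)
    stats::heatmap(x$dist, symm = TRUE)
  invisible(x)
}

#' Export the trajectory dendrogram as Newick text
#' @param x a `trajectory_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trajectory_newick <- function(x, path) {
  stopifnot(inherits(x, "trajectory_result"))
  ape::write.tree(ape::as.phylo(x$tree), file = path)
  invisible(path)
}
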
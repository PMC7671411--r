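#' Contingency table of two partitions
#'
#' @param u,v label vectors of equal length (any atomic type).
#' @return integer matrix `n_ij` of co-occurrence counts, clusters of `u`
#'   in rows, clusters of `v` in columns.
#' @export
contingency <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  if (!length(u)) stop("empty partitions")
  unclass(table(u, v))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' 1 for identical partitions, around 0 for independent ones.
#'
#' @param u,v label vectors of equal length (n >= 2).
#' @return a scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(u, v) {
  n <- length(u)
  if (n < 2) stop("ARI needs at least 2 points")
  ct <- contingency(u, v)
  sum_ij <- sum(choose(ct, 2))
  a <- sum(choose(rowSums(ct), 2))
  b <- sum(choose(colSums(ct), 2))
  exp_idx <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (max_idx == exp_idx) return(1)    # both partitions trivial/identical
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies. When both partitions are single-cluster the
#' value is 1 by convention (identical trivial partitions); when exactly
#' one has zero entropy it is 0.
#'
#' @param u,v label vectors of equal length.
#' @return a scalar in `[0, 1]`.
#' @export
normalized_mutual_information <- function(u, v) {
  ct <- contingency(u, v)
  n <- sum(ct)
  pi_ <- rowSums(ct) / n
  pj_ <- colSums(ct) / n
  hu <- -sum(pi_ * log(pi_))
  hv <- -sum(pj_ * log(pj_))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  p <- ct / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pi_[row(p)[nz]] * pj_[col(p)[nz]])))
  mi / ((hu + hv) / 2)
}

#' F1 score for rare-population detection
#'
#' Implements the spike-in evaluation protocol: the predicted rare set is
#' the smallest predicted cluster (ties broken toward the lower label in
#' sort order), unless `rare_cluster` names one explicitly; precision and
#' recall are computed against the true rare mask and combined as
#' `F1 = 2PR/(P+R)` (0 when the denominator or the predicted set is
#' empty).
#'
#' @param truth_rare logical vector marking the truly rare cells.
#' @param predicted cluster label vector of the same length.
#' @param rare_cluster optional explicit label of the predicted rare
#'   cluster (needed when k > 2 and the smallest-cluster rule is not
#'   wanted).
#' @return a scalar in `[0, 1]`.
#' @export
rare_detection_f1 <- function(truth_rare, predicted, rare_cluster = NULL) {
  if (length(truth_rare) != length(predicted))
    stop("truth and prediction differ in length")
  truth_rare <- as.logical(truth_rare)
  if (is.null(rare_cluster)) {
    sizes <- table(predicted)
    rare_cluster <- names(sizes)[which.min(sizes)]  # ties: first in sort order
  }
  pred_rare <- as.character(predicted) == as.character(rare_cluster)
  tp <- sum(pred_rare & truth_rare)
  fp <- sum(pred_rare & !truth_rare)
  fn <- sum(!pred_rare & truth_rare)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' F1 from confusion counts
#'
#' Convenience for scoring printed confusion counts directly.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts.
#' @return a scalar in `[0, 1]` (0 when `tp == 0`).
#' @export
f1_from_counts <- function(tp, fp, fn) {
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
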
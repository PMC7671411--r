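#' Specification for gamma-Poisson count simulation
#'
#' Encodes a splatter-style generative model: per-gene base means drawn
#' from a gamma distribution, multiplicative group-specific differential
#' expression factors on a random subset of genes, a lognormal per-cell
#' library-size factor, Poisson sampling, and an optional logistic
#' dropout layer keyed to the log gene mean.
#'
#' Defaults emulate the simulation world used for the dropout-robustness
#' benchmarks: 5000 cells x 10000 genes with 10 highly imbalanced groups
#' (smallest 1.5%, largest 23.2% of cells).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param group_proportions per-group cell proportions (must sum to 1);
#'   group sizes are deterministic largest-remainder rounding of
#'   `n_cells * proportions` unless `sample_proportions = TRUE`, in which
#'   case cells are assigned multinomially.
#' @param sample_proportions draw group assignment multinomially.
#' @param de_fraction fraction of genes receiving a DE factor per group.
#' @param de_strength lognormal location (meanlog) of DE factor
#'   magnitudes; factors are inverted (down-regulated) with probability
#'   1/2, as in splatter.
#' @param de_sdlog lognormal scale of DE factor magnitudes.
#' @param gamma_shape,gamma_scale gamma parameters of the per-gene base
#'   mean distribution.
#' @param lib_sigma sdlog of the per-cell lognormal library-size factor.
#' @param dropout_midpoint,dropout_shape logistic dropout parameters (see
#'   [add_dropout()]); `dropout_midpoint = NULL` disables dropout.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_cells = 5000, n_genes = 10000,
                     group_proportions = c(0.015, 0.025, 0.04, 0.06, 0.08,
                                           0.10, 0.12, 0.146, 0.182, 0.232),
                     sample_proportions = FALSE,
                     de_fraction = 0.1, de_strength = 1.0, de_sdlog = 0.4,
                     gamma_shape = 0.6, gamma_scale = 2,
                     lib_sigma = 0.25,
                     dropout_midpoint = NULL, dropout_shape = 1.5) {
  if (abs(sum(group_proportions) - 1) > 1e-8)
    stop("group_proportions must sum to 1")
  if (any(group_proportions <= 0)) stop("group proportions must be positive")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  if (gamma_shape <= 0 || gamma_scale <= 0 || lib_sigma < 0)
    stop("invalid distribution parameters")
  structure(as.list(environment()), class = "sim_spec")
}

# largest-remainder apportionment of n cells to proportions
apportion <- function(n, props) {
  raw <- n * props
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Simulate an imbalanced Gaussian mixture in embedding space
#'
#' Cluster means are drawn isotropically and rescaled so the smallest
#' inter-mean distance equals `separation`; points are unit-variance
#' isotropic normal around their mean. Used as the clustering fixture for
#' imbalance experiments.
#'
#' @param sizes per-cluster point counts.
#' @param d dimension (>= 1).
#' @param separation nearest inter-mean distance (0 collapses all
#'   clusters).
#' @return list with `points` (N x d) and `labels` (1..length(sizes)).
#' @export
simulate_gaussian_mixture <- function(sizes, d, separation) {
  if (d < 1) stop("d must be >= 1")
  if (any(sizes < 1)) stop("all cluster sizes must be >= 1")
  k <- length(sizes)
  means <- matrix(stats::rnorm(k * d), k, d)
  if (k > 1) {
    dmin <- min(stats::dist(means))
    means <- if (dmin > 0) means * (separation / dmin)
    else means * 0
  }
  labels <- rep(seq_len(k), sizes)
  points <- means[labels, , drop = FALSE] +
    matrix(stats::rnorm(sum(sizes) * d), sum(sizes), d)
  list(points = points, labels = labels)
}

#' Simulate single-cell counts from a gamma-Poisson model
#'
#' @param spec a [sim_spec()].
#' @return list with `matrix` (an `ExpressionMatrix`, raw layer),
#'   `labels` (group per cell), `sparsity` (realized zero fraction) and
#'   `group_sizes`.
#' @export
simulate_counts <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  k <- length(spec$group_proportions)
  labels <- if (spec$sample_proportions)
    sample.int(k, spec$n_cells, replace = TRUE, prob = spec$group_proportions)
  else rep(seq_len(k), apportion(spec$n_cells, spec$group_proportions))
  if (length(labels) != spec$n_cells) stop("group sizes do not sum to n_cells")

  base <- stats::rgamma(spec$n_genes, shape = spec$gamma_shape,
                        scale = spec$gamma_scale)
  # group x gene DE factor matrix
  de <- matrix(1, k, spec$n_genes)
  n_de <- round(spec$de_fraction * spec$n_genes)
  for (g in seq_len(k)) {
    idx <- sample.int(spec$n_genes, n_de)
    fac <- stats::rlnorm(n_de, meanlog = spec$de_strength,
                         sdlog = spec$de_sdlog)
    flip <- stats::runif(n_de) < 0.5
    fac[flip] <- 1 / fac[flip]
    de[g, idx] <- fac
  }
  lib <- stats::rlnorm(spec$n_cells, sdlog = spec$lib_sigma)

  counts <- matrix(0L, spec$n_cells, spec$n_genes)
  for (g in seq_len(k)) {
    rows <- which(labels == g)
    mu <- outer(lib[rows], base * de[g, ])
    counts[rows, ] <- matrix(stats::rpois(length(mu), mu),
                             nrow = length(rows))
  }
  m <- expression_matrix(counts, layer = "raw")
  if (!is.null(spec$dropout_midpoint))
    m <- add_dropout(m, spec$dropout_midpoint, spec$dropout_shape)
  list(matrix = m, labels = labels,
       sparsity = mean(m$values == 0),
       group_sizes = as.integer(table(factor(labels, levels = seq_len(k)))))
}

#' Zero entries by a logistic dropout model
#'
#' Each entry of gene `g` is zeroed independently with probability
#' `plogis(shape * (midpoint - log(mean_g + 1)))`, where `mean_g` is the
#' gene's mean count in the input matrix: weakly expressed genes drop out
#' more. Raising `midpoint` raises the expected sparsity.
#'
#' @param m an `ExpressionMatrix`, raw layer.
#' @param midpoint log-mean at which dropout probability is 1/2.
#' @param shape positive logistic steepness.
#' @return the thinned `ExpressionMatrix` (raw layer).
#' @export
add_dropout <- function(m, midpoint, shape = 1.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw") stop("add_dropout expects the raw layer")
  v <- as.matrix(m$values)
  p <- stats::plogis(shape * (midpoint - log(Matrix::colMeans(m$values) + 1)))
  drop <- matrix(stats::runif(length(v)), nrow(v), ncol(v)) <
    matrix(p, nrow(v), ncol(v), byrow = TRUE)
  v[drop] <- 0
  expression_matrix(v, cell_ids = m$cell_ids, gene_ids = m$gene_ids,
                    layer = "raw")
}

#' Expected sparsity after logistic dropout (no RNG)
#'
#' @param m raw `ExpressionMatrix`.
#' @param midpoint,shape dropout parameters as in [add_dropout()].
#' @return expected zero fraction after dropout.
#' @export
expected_sparsity <- function(m, midpoint, shape = 1.5) {
  v <- as.matrix(m$values)
  p <- stats::plogis(shape * (midpoint - log(colMeans(v) + 1)))
  zero_now <- colMeans(v == 0)
  mean(zero_now + (1 - zero_now) * p)
}

#' Calibrate the dropout midpoint to a target sparsity
#'
#' Bisects on `midpoint` using the deterministic [expected_sparsity()]
#' curve, which is monotone increasing in `midpoint`.
#'
#' @param m raw `ExpressionMatrix` before dropout.
#' @param target desired zero fraction (must be >= the matrix's current
#'   sparsity).
#' @param shape logistic steepness.
#' @param tol bisection tolerance on sparsity.
#' @return the calibrated midpoint.
#' @export
calibrate_dropout_midpoint <- function(m, target, shape = 1.5, tol = 1e-4) {
  cur <- mean(as.matrix(m$values) == 0)
  if (target < cur)
    stop(sprintf("target sparsity %.3f below current %.3f", target, cur))
  lo <- -30; hi <- 30
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (expected_sparsity(m, mid, shape) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Spike a rare population into an abundant one
#'
#' Simulates a two-population count matrix from a shared gamma base-mean
#' profile in which the rare population carries its own differential
#' expression factors of strength `shift_strength`; mimics cell-line
#' spike-in mixtures used for rare-type detection benchmarks (e.g. 40
#' rare cells among 1580).
#'
#' @param n_abundant,n_rare population sizes (`n_rare >= 1`,
#'   `n_abundant >= n_rare`).
#' @param base_spec a [sim_spec()] supplying genes/base-mean/dropout
#'   settings (its group structure is ignored).
#' @param shift_strength DE factor meanlog separating the rare
#'   population; 0 makes the populations exchangeable.
#' @return list with `matrix` (raw `ExpressionMatrix`), `rare_mask`
#'   (logical, TRUE for rare cells), `labels` (1 abundant, 2 rare).
#' @export
spike_rare_mixture <- function(n_abundant, n_rare,
                               base_spec = sim_spec(), shift_strength = 1.0) {
  if (n_rare < 1) stop("n_rare must be >= 1")
  if (n_abundant < n_rare) stop("n_abundant must be >= n_rare")
  n <- n_abundant + n_rare
  spec <- sim_spec(n_cells = n, n_genes = base_spec$n_genes,
                   group_proportions = c(n_abundant, n_rare) / n,
                   de_fraction = base_spec$de_fraction,
                   de_strength = shift_strength,
                   de_sdlog = base_spec$de_sdlog,
                   gamma_shape = base_spec$gamma_shape,
                   gamma_scale = base_spec$gamma_scale,
                   lib_sigma = base_spec$lib_sigma,
                   dropout_midpoint = base_spec$dropout_midpoint,
                   dropout_shape = base_spec$dropout_shape)
  if (shift_strength == 0) spec$de_fraction <- 0
  sim <- simulate_counts(spec)
  list(matrix = sim$matrix, rare_mask = sim$labels == 2L,
       labels = sim$labels)
}
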
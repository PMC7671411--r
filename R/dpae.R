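#' Configuration for the distance-preserving autoencoder embedding (DPAE)
#'
#' The embedding couples two feed-forward networks trained on mini-batches
#' of cell pairs: an imputation autoencoder `f_a: R^G -> R^G` that denoises
#' expression vectors (correcting dropout events), and an MDS-style encoder
#' `f_m: R^G -> R^d` trained so that squared Euclidean distances between
#' embedded cells track squared distances between the *imputed* vectors.
#'
#' @param latent_dim embedding dimension `d` (default 256); must be smaller
#'   than the number of genes.
#' @param ae_hidden hidden widths of the autoencoder's encoder half; the
#'   decoder mirrors them. Default `c(1024, 512)`, giving
#'   G-1024-512-latent-512-1024-G.
#' @param mds_hidden hidden widths of the MDS encoder (default
#'   `c(1024, 512)`).
#' @param alpha weight of the distance-preservation loss in the joint
#'   objective `L = L_rec + alpha * L_mds`; must be positive.
#' @param dropout_rate dropout probability on the autoencoder's hidden
#'   layers during training (regularization), in `[0, 1)`.
#' @param pretrain_steps autoencoder-only training steps (stage 1).
#' @param max_joint_steps ceiling on joint-tuning steps (stage 2).
#' @param batch_pairs number of cell pairs per mini-batch.
#' @param lr Adam learning rate.
#' @param early_stop stop stage 2 once the smoothed joint loss stops
#'   improving by `tol` (relative) within a `patience`-step window.
#' @param tol,patience early-stopping tolerance and window.
#' @param center subtract per-gene means before feeding the networks
#'   (distances are translation-invariant; centering removes the dominant
#'   mean component that otherwise saturates early optimizer moments).
#' @param svd_init warm-start the first encoder layer of both networks
#'   (and the matching decoder output layer) with the top right singular
#'   vectors of the centered data, computed by a randomized SVD. This
#'   skips the slow stochastic discovery of the principal subspace;
#'   training then refines it nonlinearly.
#' @param seed integer seed controlling initialization, pair sampling and
#'   dropout masks.
#' @return a `dpae_config` list.
#' @export
dpae_config <- function(latent_dim = 256,
                        ae_hidden = c(1024, 512),
                        mds_hidden = c(1024, 512),
                        alpha = 1.0,
                        dropout_rate = 0.3,
                        pretrain_steps = 1000,
                        max_joint_steps = 40000,
                        batch_pairs = 256,
                        lr = 1e-3,
                        early_stop = TRUE,
                        tol = 1e-4,
                        patience = 100,
                        center = TRUE,
                        svd_init = TRUE,
                        seed = 1L) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (latent_dim < 1 || batch_pairs < 1) stop("invalid config")
  structure(as.list(environment()), class = "dpae_config")
}

#' Sample a mini-batch of cell pairs
#'
#' Pairs are drawn uniformly with `i != j`, independently across the batch
#' (with replacement across batches: enumerating all N^2 pairs is never
#' required).
#'
#' @param n_cells number of cells N (>= 2).
#' @param batch_pairs number of pairs to draw.
#' @return integer matrix with columns `i`, `j`.
#' @export
sample_pair_batch <- function(n_cells, batch_pairs) {
  if (n_cells < 2) stop("need at least 2 cells to form pairs")
  if (batch_pairs < 1) stop("batch_pairs must be >= 1")
  i <- sample.int(n_cells, batch_pairs, replace = TRUE)
  # draw j from the n-1 others by skipping i
  j <- sample.int(n_cells - 1L, batch_pairs, replace = TRUE)
  j <- j + (j >= i)
  cbind(i = i, j = j)
}

#' Autoencoder reconstruction loss over a pair batch
#'
#' `L_rec = (1 / (2|Dp|)) * sum_pairs (||x_i - xhat_i||^2 + ||x_j - xhat_j||^2)`
#'
#' @param x_i,x_j observed expression rows for the two pair members
#'   (P x G matrices).
#' @param xhat_i,xhat_j corresponding imputed rows.
#' @return a non-negative scalar.
#' @export
reconstruction_loss <- function(x_i, x_j, xhat_i, xhat_j) {
  x_i <- rbind(x_i); x_j <- rbind(x_j)
  xhat_i <- rbind(xhat_i); xhat_j <- rbind(xhat_j)
  if (!all(dim(x_i) == dim(xhat_i)) || !all(dim(x_j) == dim(xhat_j)) ||
      nrow(x_i) != nrow(x_j))
    stop("shape mismatch between observed and imputed pair matrices")
  P <- nrow(x_i)
  (sum((x_i - xhat_i)^2) + sum((x_j - xhat_j)^2)) / (2 * P)
}

#' Distance-preservation (MDS) loss over a pair batch
#'
#' `L_mds = (1/|Dp|) * sum_pairs | ||z_i - z_j||^2 - ||xhat_i - xhat_j||^2 |`
#' with Euclidean distance on the imputed vectors.
#'
#' @param z_i,z_j embedded rows (P x d).
#' @param xhat_i,xhat_j imputed expression rows (P x G).
#' @return a non-negative scalar.
#' @export
mds_loss <- function(z_i, z_j, xhat_i, xhat_j) {
  z_i <- rbind(z_i); z_j <- rbind(z_j)
  xhat_i <- rbind(xhat_i); xhat_j <- rbind(xhat_j)
  P <- nrow(z_i)
  if (nrow(z_j) != P || nrow(xhat_i) != P || nrow(xhat_j) != P)
    stop("pair count mismatch between embedding and imputed matrices")
  dz2 <- rowSums((z_i - z_j)^2)
  dx2 <- rowSums((xhat_i - xhat_j)^2)
  mean(abs(dz2 - dx2))
}

#' Joint training objective
#' @param rec reconstruction loss value.
#' @param mds distance-preservation loss value.
#' @param alpha positive weight on `mds`.
#' @return `rec + alpha * mds`.
#' @export
joint_loss <- function(rec, mds, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  rec + alpha * mds
}

#' Train the distance-preserving autoencoder embedding
#'
#' Two-stage training on mini-batches of cell pairs. Stage 1 (pre-training)
#' fits the imputation autoencoder alone by minimizing the reconstruction
#' loss. Stage 2 (joint tuning) minimizes `L_rec + alpha * L_mds`, with
#' gradients of the distance term flowing through both networks, until
#' `max_joint_steps` or early stopping on the smoothed joint loss.
#'
#' @param m an `ExpressionMatrix` with `layer = "lognorm"`.
#' @param cfg a [dpae_config()].
#' @return a `dpae_model`: both networks, the config, and a `training_log`
#'   data.frame with per-step stage, reconstruction, distance and total
#'   loss values.
#' @export
train_dpae <- function(m, cfg = dpae_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(cfg, "dpae_config"))
  if (m$layer != "lognorm")
    stop("train_dpae expects the lognorm layer (run normalize_and_log)")
  X <- em_dense(m)
  N <- nrow(X); G <- ncol(X)
  if (N < 2) stop("need at least 2 cells")
  if (cfg$latent_dim >= G)
    stop("latent_dim must be < number of genes (", G, ")")

  set.seed(cfg$seed)
  mu <- if (cfg$center) colMeans(X) else rep(0, G)
  X <- sweep(X, 2, mu)
  ae <- mlp_init(c(G, cfg$ae_hidden, cfg$latent_dim,
                   rev(cfg$ae_hidden), G))
  md <- mlp_init(c(G, cfg$mds_hidden, cfg$latent_dim))
  if (cfg$svd_init) {
    V <- rsvd_right(X, max(cfg$ae_hidden[1], cfg$mds_hidden[1]))
    if (!is.null(V)) {
      r1 <- min(ncol(V), cfg$ae_hidden[1])
      ae$layers[[1]]$W[, seq_len(r1)] <- V[, seq_len(r1)]
      last <- length(ae$layers)
      ae$layers[[last]]$W[seq_len(r1), ] <- t(V[, seq_len(r1)])
      r2 <- min(ncol(V), cfg$mds_hidden[1])
      md$layers[[1]]$W[, seq_len(r2)] <- V[, seq_len(r2)]
    }
  }
  ae_opt <- adam_init(ae); md_opt <- adam_init(md)

  log_stage <- character(0); log_step <- integer(0)
  log_rec <- numeric(0); log_mds <- numeric(0); log_tot <- numeric(0)
  P <- cfg$batch_pairs

  # ---- stage 1: pre-train the autoencoder on L_rec ----
  for (step in seq_len(cfg$pretrain_steps)) {
    pb <- sample_pair_batch(N, P)
    Xb <- X[c(pb[, 1], pb[, 2]), , drop = FALSE]
    fwd <- mlp_forward(ae, Xb, cfg$dropout_rate, training = TRUE)
    diff <- fwd$out - Xb
    rec <- sum(diff^2) / (2 * P)
    if (!is.finite(rec))
      stop("non-finite reconstruction loss at pre-training step ", step)
    up <- adam_step(ae, mlp_backward(ae, fwd, diff / P), ae_opt, step, cfg$lr)
    ae <- up$net; ae_opt <- up$state
    log_stage <- c(log_stage, "pretrain"); log_step <- c(log_step, step)
    log_rec <- c(log_rec, rec); log_mds <- c(log_mds, NA_real_)
    log_tot <- c(log_tot, rec)
  }

  # ---- stage 2: joint tuning of both networks ----
  best <- Inf; wait <- 0L; ema <- NA_real_
  for (step in seq_len(cfg$max_joint_steps)) {
    pb <- sample_pair_batch(N, P)
    idx <- c(pb[, 1], pb[, 2])
    Xb <- X[idx, , drop = FALSE]
    fa <- mlp_forward(ae, Xb, cfg$dropout_rate, training = TRUE)
    fm <- mlp_forward(md, Xb, 0, training = FALSE)
    xhat <- fa$out
    z <- fm$out
    ii <- seq_len(P); jj <- P + ii
    ddz <- z[ii, , drop = FALSE] - z[jj, , drop = FALSE]
    ddx <- xhat[ii, , drop = FALSE] - xhat[jj, , drop = FALSE]
    dz2 <- rowSums(ddz^2); dx2 <- rowSums(ddx^2)
    rec <- sum((xhat - Xb)^2) / (2 * P)
    mds <- mean(abs(dz2 - dx2))
    tot <- rec + cfg$alpha * mds
    if (!is.finite(tot)) stop("non-finite joint loss at step ", step)

    s <- sign(dz2 - dx2)
    dXhat <- (xhat - Xb) / P +
      cfg$alpha * rbind(-(2 / P) * s * ddx, (2 / P) * s * ddx)
    dZ <- cfg$alpha * rbind((2 / P) * s * ddz, -(2 / P) * s * ddz)
    up <- adam_step(ae, mlp_backward(ae, fa, dXhat), ae_opt, step, cfg$lr)
    ae <- up$net; ae_opt <- up$state
    up <- adam_step(md, mlp_backward(md, fm, dZ), md_opt, step, cfg$lr)
    md <- up$net; md_opt <- up$state

    log_stage <- c(log_stage, "joint"); log_step <- c(log_step, step)
    log_rec <- c(log_rec, rec); log_mds <- c(log_mds, mds)
    log_tot <- c(log_tot, tot)

    if (cfg$early_stop) {
      ema <- if (is.na(ema)) tot else 0.99 * ema + 0.01 * tot
      if (step > cfg$patience) {
        if (best - ema > cfg$tol * abs(best)) { best <- ema; wait <- 0L }
        else wait <- wait + 1L
        if (wait >= cfg$patience) break
      } else best <- min(best, ema)
    }
  }

  structure(list(
    ae = ae, mds = md, config = cfg, n_genes = G, mu = mu,
    training_log = data.frame(stage = log_stage, step = log_step,
                              rec = log_rec, mds = log_mds,
                              total = log_tot)),
    class = "dpae_model")
}

#' @export
print.dpae_model <- function(x, ...) {
  nj <- sum(x$training_log$stage == "joint")
  cat(sprintf("dpae_model: G = %d, d = %d; %d pretrain + %d joint steps\n",
              x$n_genes, x$config$latent_dim,
              sum(x$training_log$stage == "pretrain"), nj))
  cat(sprintf("  final joint loss: %.4g\n",
              utils::tail(x$training_log$total, 1)))
  invisible(x)
}

# chunked inference-mode forward pass
dpae_infer <- function(net, X, chunk = 2048L) {
  out <- NULL
  for (start in seq(1L, nrow(X), by = chunk)) {
    end <- min(start + chunk - 1L, nrow(X))
    o <- mlp_forward(net, X[start:end, , drop = FALSE])$out
    out <- if (is.null(out)) o else rbind(out, o)
  }
  out
}

#' Embed cells with a trained model
#'
#' Applies the MDS encoder in inference mode (dropout disabled).
#'
#' @param model a `dpae_model`.
#' @param m an `ExpressionMatrix` (lognorm) with the same gene count the
#'   model was trained on.
#' @return numeric N x d matrix, rownames = cell ids.
#' @export
embed_cells <- function(model, m) {
  stopifnot(inherits(model, "dpae_model"), inherits(m, "ExpressionMatrix"))
  X <- em_dense(m)
  if (ncol(X) != model$n_genes)
    stop("matrix has ", ncol(X), " genes but model expects ", model$n_genes)
  z <- dpae_infer(model$mds, sweep(X, 2, model$mu))
  rownames(z) <- m$cell_ids
  z
}

#' Impute expression with a trained model
#'
#' Applies the autoencoder in inference mode; the output is a denoised
#' G-dimensional expression vector per cell on the lognorm scale.
#'
#' @inheritParams embed_cells
#' @return numeric N x G matrix, dimnames from `m`.
#' @export
impute_expression <- function(model, m) {
  stopifnot(inherits(model, "dpae_model"), inherits(m, "ExpressionMatrix"))
  X <- em_dense(m)
  if (ncol(X) != model$n_genes)
    stop("matrix has ", ncol(X), " genes but model expects ", model$n_genes)
  xhat <- dpae_infer(model$ae, sweep(X, 2, model$mu))
  xhat <- sweep(xhat, 2, model$mu, "+")
  dimnames(xhat) <- list(m$cell_ids, m$gene_ids)
  xhat
}
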
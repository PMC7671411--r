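# Minimal dense feed-forward networks with manual backprop + Adam.
# Rows of X are samples; layer l computes A_l = act(A_{l-1} %*% W_l + b_l),
# with a linear output layer. Hidden activation is ReLU. Gradients are
# accumulated for mean-type losses whose dOut is already scaled.

mlp_init <- function(widths) {
  # widths: c(in, hidden..., out); He initialization on hidden, Glorot-ish out
  L <- length(widths) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    sd <- sqrt(2 / fan_in)
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * widths[l + 1], sd = sd),
                 fan_in, widths[l + 1]),
      b = rep(0, widths[l + 1]))
  }
  structure(list(layers = layers, widths = widths), class = "mlp")
}

# forward pass; dropout (inverted) on hidden activations when training
mlp_forward <- function(net, X, dropout_rate = 0, training = FALSE) {
  L <- length(net$layers)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$layers[[l]]$W
    Z <- sweep(Z, 2, net$layers[[l]]$b, "+")
    if (l < L) {
      A <- pmax(Z, 0)
      if (training && dropout_rate > 0) {
        mask <- matrix(stats::runif(length(A)) >= dropout_rate,
                       nrow(A), ncol(A)) / (1 - dropout_rate)
        A <- A * mask
        masks[[l]] <- mask
      }
    } else A <- Z
    acts[[l + 1]] <- A
  }
  list(out = acts[[L + 1]], acts = acts, masks = masks)
}

# dOut: gradient of the loss wrt the network output (same shape as out)
mlp_backward <- function(net, fwd, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) {
      if (!is.null(fwd$masks[[l]])) dA <- dA * fwd$masks[[l]]
      dA <- dA * (fwd$acts[[l + 1]] > 0)
    }
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]], dA),
                       b = colSums(dA))
    if (l > 1) dA <- dA %*% t(net$layers[[l]]$W)
  }
  grads
}

# randomized range-finder SVD: top-r right singular vectors of X (n x G)
rsvd_right <- function(X, r, oversample = 12L) {
  r <- min(r, nrow(X) - 1L, ncol(X))
  if (r < 1) return(NULL)
  Om <- matrix(stats::rnorm(ncol(X) * (r + oversample)), ncol(X))
  Q <- qr.Q(qr(X %*% Om))
  sv <- svd(crossprod(Q, X), nu = 0, nv = r)
  sv$v
}

adam_init <- function(net) {
  lapply(net$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0,
         mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(net, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}
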
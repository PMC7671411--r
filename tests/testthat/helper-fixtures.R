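# shared fixtures and independent oracles (kept deliberately naive)

# well-separated k-group count fixture on the lognorm layer
make_lognorm_clusters <- function(n_cells = 120, n_genes = 80, k = 3,
                                  seed = 1, de_fraction = 0.25,
                                  de_strength = 1.5) {
  set.seed(seed)
  sim <- simulate_counts(sim_spec(
    n_cells = n_cells, n_genes = n_genes,
    group_proportions = rep(1 / k, k),
    de_fraction = de_fraction, de_strength = de_strength))
  list(ml = normalize_and_log(filter_min_count(sim$matrix)),
       raw = sim$matrix, labels = sim$labels)
}

# brute-force ARI by explicit pair counting over all n(n-1)/2 pairs
ari_bruteforce <- function(u, v) {
  n <- length(u)
  a <- b <- c_ <- d <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    su <- u[i] == u[j]; sv <- v[i] == v[j]
    if (su && sv) a <- a + 1
    else if (su && !sv) b <- b + 1
    else if (!su && sv) c_ <- c_ + 1
    else d <- d + 1
  }
  np <- a + b + c_ + d
  exp_a <- (a + b) * (a + c_) / np
  max_a <- ((a + b) + (a + c_)) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

# brute-force NMI from explicit probability sums
nmi_bruteforce <- function(u, v) {
  n <- length(u)
  us <- unique(u); vs <- unique(v)
  hu <- 0; hv <- 0; mi <- 0
  for (a_ in us) { p <- sum(u == a_) / n; hu <- hu - p * log(p) }
  for (b_ in vs) { p <- sum(v == b_) / n; hv <- hv - p * log(p) }
  for (a_ in us) for (b_ in vs) {
    pab <- sum(u == a_ & v == b_) / n
    if (pab > 0)
      mi <- mi + pab * log(pab / ((sum(u == a_) / n) * (sum(v == b_) / n)))
  }
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi / ((hu + hv) / 2)
}

# brute-force hypergeometric upper tail over the full support
hyper_tail_bruteforce <- function(n_bg, a, b, k) {
  if (k == 0) return(1)
  i <- k:min(a, b)
  sum(choose(a, i) * choose(n_bg - a, b - i)) / choose(n_bg, b)
}

# write a tiny mtx + sidecars (10x orientation: genes as rows)
write_mtx_fixture <- function(dir, counts_cells_by_genes, cells, genes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(counts_cells_by_genes), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cells, file.path(dir, "barcodes.tsv"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  file.path(dir, "matrix.mtx")
}
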
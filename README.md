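# cellsketch

Unsupervised clustering of single-cell RNA-seq count matrices, for
analysts who need *rare* populations to survive clustering. Two pieces
work together:

1. **DPAE** — a distance-preserving autoencoder embedding. An imputation
   autoencoder `f_a: R^G -> R^G` denoises expression profiles (dropout
   events), and an MDS-style encoder `f_m: R^G -> R^d` is trained on
   mini-batches of cell pairs so that
   `||z_i - z_j||^2 ≈ ||x̂_i - x̂_j||^2`, i.e. Euclidean geometry in the
   embedding reflects distances between *imputed* profiles. Joint loss:
   `L = L_rec + α L_mds`.
2. **RPH-kmeans** — k-means initialized from a weighted *skeleton* built
   by iterative random-projection hashing
   (`h_{a,b}(v) = floor((a·v + b)/w)`, `a ~ N(0, I)`, `b ~ U(0, w)`).
   Colliding points merge into weighted centroids; iterating collapses
   dense regions by orders of magnitude while small distant populations
   survive as their own weighted points, so k-means++ seeding on the
   skeleton is not biased toward large clusters the way it is on raw
   data.

Also included: weighted-BIC selection of the number of clusters,
ARI/NMI, a rare-population detection F1 protocol, Wilcoxon rank-sum
marker calling with hypergeometric cell-type enrichment, cluster-level
trajectory dendrograms, and a gamma-Poisson simulator with logistic
dropout so the whole pipeline is testable offline.

## Worked example

```r
library(cellsketch)

# simulate 600 cells x 400 genes in three groups, then cluster them
set.seed(1)
sim <- simulate_counts(sim_spec(n_cells = 600, n_genes = 400,
                                group_proportions = c(0.1, 0.3, 0.6),
                                de_fraction = 0.25, de_strength = 1.5))
res <- run_pipeline(sim$matrix, outdir = "demo_out",
                    dpae = dpae_config(latent_dim = 16, ae_hidden = 64,
                                       mds_hidden = 64, pretrain_steps = 300,
                                       max_joint_steps = 1000,
                                       batch_pairs = 128, dropout_rate = 0.1),
                    k = 3, seed = 1)
adjusted_rand_index(sim$labels, res$labels)
table(truth = sim$labels, predicted = res$labels)
```

Output from this exact script:

```
#> [1] 1
#>      predicted
#> truth   1   2   3
#>     1   0   0  60
#>     2 180   0   0
#>     3   0 360   0
```

ARI = 1 means the predicted partition matches the planted groups
exactly (cluster numbering is arbitrary — here planted group 1 came out
as predicted cluster 3, and so on). `demo_out/` now contains
`cells_labels.tsv`, `cells_embedding.tsv`, `centers.tsv`,
`markers.tsv`, `trajectory.nwk` and a `manifest.json` with seeds,
parameters and timings; rerunning with the same seed reproduces the
labels exactly.

On the imbalance benchmark the package is built around (two 10-D
Gaussians, 2000 vs 50 points, means 6 apart, single initialization),
`rph_kmeans()` averages ARI ≈ 0.97 over 20 seeds while k-means++ Lloyd
averages ≈ 0.04, because the SSE-optimal k = 2 solution on such data
*splits the large cluster* — only a well-placed initialization recovers
the small population.

## Command line

```sh
Rscript -e 'cellsketch::cellsketch_cli()' simulate --n-cells 600 --n-genes 400 --outdir sim
Rscript -e 'cellsketch::cellsketch_cli()' run --input sim/matrix.mtx --k 3 --outdir out --seed 1
Rscript -e 'cellsketch::cellsketch_cli()' score --truth sim/labels.tsv --predicted out/cells_labels.tsv
```

Subcommands `preprocess`, `embed`, `cluster`, `estimate-k` and
`annotate` expose the individual stages; each consumes the previous
stage's files so you can substitute your own embedding or labels.

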
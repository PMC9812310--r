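# dodist

Distance-of-distance (DoD) transformation of dissimilarity matrices for
high-dimensional data that contain scattering noise.

## The problem

t-SNE and UMAP embeddings break down when many of the points are noise
scattered uniformly in a high-dimensional space: the noise points are
mutually distant, repel each other in the embedding, and end up spread over
— and interleaved with — the genuine clusters. This hits exactly the data
sets these tools are popular for: population spike-train patterns (where
spontaneous-activity epochs scatter among stimulus-evoked clusters),
single-cell profiles, deep-network image representations.

## The transform

Given a symmetric dissimilarity matrix $D = (d_{i,j})$ and the
$K$-nearest-neighbor sets $I$ and $J$ of points $i$ and $j$, the DoD
transformation replaces $d_{i,j}$ by

$$
f_{i,j} \;=\; \frac{1}{2K}\Big(\sum_{n \in I} |d_{n,i}-d_{n,j}|
\;+\; \sum_{m \in J} |d_{m,i}-d_{m,j}|\Big).
$$

In high dimension two scattered points have nearly identical distances to
any reference point, so $f_{i,j} \to 0$ for noise pairs even when
$d_{i,j}$ is large, while cluster geometry is preserved (for metric inputs,
$f_{i,j} \le d_{i,j}$ entrywise). Under the idealization of
infinitely-dense clusters and the normalized L1 metric, the expected
transformed distances for cluster–noise and noise–noise pairs are
$d - \tfrac16 (1/N)^{1/D}$ and $d - \tfrac13 (1/N)^{1/D}$: as $D \to
\infty$ they approach $1/6$ and $0$, so noise collapses into its own tight
group separated from every cluster. The package implements the transform,
these closed-form predictions, the synthetic benchmark generators, and an
evaluation harness (t-SNE/UMAP embedding, K-means + adjusted Rand index,
cross-validated KNN on precomputed dissimilarities, and an unsupervised
noise detector based on neighborhood-overlap rates).

## Worked example

```r
library(dodist)

## 5 Gaussian clusters (20 points, sd 0.1) + 200 uniform noise points, D = 50
pc <- sim_noisy_gaussians(5, 20, 200, 50, sd = 0.1, seed = 11)
d  <- dist_matrix(pc, "l2")
f  <- dod_transform(d, k = 10)

measure_shrinkage(d, f, pc$labels)
#>         pair_type n_pairs mean_original mean_transformed     delta  fraction
#> 1 cluster-cluster    4000      2.982308        2.0342087 0.9480997 0.6820920
#> 2   cluster-noise   20000      2.977367        1.2773047 1.7000622 0.4290048
#> 3     noise-noise   19900      2.899022        0.4483554 2.4506670 0.1546574

## noise-noise distances shrink to 15% of their original mean, cluster-noise
## to 43%: the noise coalesces while staying separated from the clusters.

emb <- embed_2d(f, perplexity = 30, seed = 2)
cluster_and_score(emb, pc$labels, seed = 2)
#> clustering_eval: 300 points, 6 clusters, ARI = 1.000

## unsupervised noise detection (overlap of 20-NN sets before/after)
call <- detect_noise(d, f, k = 20, threshold = 0.65)
score_noise_call(call, pc$labels)["f1"]
#> f1
#>  1
```

On the same data the embedding of the *original* matrix interleaves the
noise with the clusters and K-means ARI collapses. The
closed-form predictions are available directly:

```r
theory_prediction(n_points = 200, dimensionality = 5000)
#> theory_prediction (N = 200, D = 5000, d = 0.3333):
#>   E nn distance 0.3330 | f cluster-noise 0.1668 | f noise-noise 0.0004 | gap 0.1665
```

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dod.R", package = "dodist"))')
Rscript $CLI transform --input D.tsv --k 10 --output F.tsv
Rscript $CLI replicate --figure fig3 --output-dir out/ --seeds 1,2,3
```

Subcommands: `transform`, `simulate`, `evaluate`, `detect-noise`,
`replicate` (scripted benchmark scenarios writing tidy TSV tables and
PDF scatter plots).

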
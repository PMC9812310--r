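---
title: "The distance-of-distance transformation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The distance-of-distance transformation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dodist)
```

## The scattering noise problem

Neighbor-embedding methods (t-SNE, UMAP) place points so that near
neighbors attract and distant points repel. When a data set mixes genuine
clusters with points scattered uniformly in a high-dimensional space, the
scattered points are mutually distant, repel each other, and spread across
the whole embedding — ending up interleaved with the clusters they should
be separated from. Raising perplexity or preprocessing with PCA does not
remove the effect; it is a property of the distance structure, not of the
optimizer.

The distance-of-distance (DoD) transformation attacks the distance
structure directly. For points $i, j$ with nearest-neighbor sets $I, J$
(each of size $K$), the original dissimilarity $d_{i,j}$ is replaced by

$$
f_{i,j} \;=\; \frac{1}{2K}\Big(\sum_{n \in I} \lvert d_{n,i}-d_{n,j}\rvert
 \;+\; \sum_{m \in J} \lvert d_{m,i}-d_{m,j}\rvert\Big).
$$

The intuition: in high dimension, two scattered points have nearly
identical distances to *any* reference point (distance concentration), so
every term is small and $f_{i,j}$ collapses even when $d_{i,j}$ is large.
Points inside a dense cluster keep their geometry, because a reference
neighbor drawn from the same cluster sits at distance $\approx 0$ from one
point and $\approx d_{i,j}$ from the other, reproducing the original
distance.

## Conventions fixed by this implementation

The defining sum leaves several details open; `dod_transform()` fixes them
as follows, and `dod_transform_oracle()` (a literal loop-by-loop
re-implementation kept for testing) fixes them identically:

* **Self-exclusion.** A point is never its own neighbor. Including it
  would add a constant $\lvert 0 - d_{i,j}\rvert$ term that merely
  double-counts the raw distance.
* **Partner inclusion.** $j$ may legitimately appear in $I$; its term then
  equals $d_{i,j}$, anchoring $F$ to $D$. It is not excluded.
* **Overlapping neighborhoods.** $I$ and $J$ are summed separately with
  normalization $1/2K$; a reference point lying in both sets contributes
  one term to each sum.
* **Tie-breaking.** Neighbor lists are ordered by ascending distance with
  ties broken by ascending index — deterministic and seed-free.
* **Bounds on `k`.** Any $1 \le k \le N-1$ is accepted, but when labels
  are supplied and `k` reaches the smallest declared cluster size a
  warning is emitted: reference sets then spill out of the cluster, and
  the transform is known to degrade as $k \to N$.
* **Input validation.** Precomputed matrices are accepted if symmetric
  within a small relative tolerance (default $10^{-8}$; external tools
  carry round-off asymmetry), with a zero diagonal and non-negative finite
  entries; they are symmetrized by averaging.
* **Complexity.** $O(N^2 k)$ time and $O(N^2)$ memory. The full matrix is
  required by construction; no sparse or landmark variant is attempted.

Useful exact identities (all enforced by the test suite): the transform is
symmetric with zero diagonal; for $N = 2$, $k = 1$ it is the identity;
duplicate points collapse to $f = 0$; if the input obeys the triangle
inequality then $\lvert d_{n,i}-d_{n,j}\rvert \le d_{i,j}$ for every $n$,
hence $f_{i,j} \le d_{i,j}$ entrywise; and the transform commutes with any
relabeling of the points.

## Closed-form predictions

The analysis idealizes clusters as *infinitely dense* (all member points
coincident), with cluster centers and noise uniform in the unit hypercube,
and uses the normalized L1 metric (Manhattan distance divided by $D$), so
distances stay finite as $D \to \infty$; the expected distance between two
uniform points tends to $1/3$. For $N$ scattered points, the expected
distance to the first nearest neighbor is approximately

$$
E\{d_{\sigma,\sigma^*}\} \approx \tfrac{1}{3}\,(1/N)^{1/D},
$$

and with a joint neighborhood of size 2 (one nearest neighbor per point)
the expected transformed distances are

$$
E\{f_{j,\sigma}\} \approx d - \tfrac{1}{6}(1/N)^{1/D}, \qquad
E\{f_{\sigma,\epsilon}\} \approx d - \tfrac{1}{3}(1/N)^{1/D},
$$

for cluster-noise and noise-noise pairs at original distance $d$. As $D$
grows the two tend to $1/6$ and $0$: noise collapses onto itself while
staying separated from the clusters by the gap $\tfrac16 (1/N)^{1/D}$.
These are implemented in `expected_nn_distance()`,
`expected_dod_cluster_noise()` and `expected_dod_noise_noise()`; the gap
identity holds exactly for all arguments, and the test suite verifies the
asymptotes by simulation (`sim_theory_scenario()` at $D$ up to 5000).

Two deliberate choices here:

* **The sample-size bound.** Requiring the gap to exceed a threshold
  $\theta$ and solving $\tfrac16 (1/N)^{1/D} > \theta$ gives
  $\log N < -D \log(6\theta)$ (natural logarithm). A widely quoted variant,
  $\log N < -6 D \log\theta$, is *not* the algebraic inversion of the gap
  formula; `shrinkage_threshold_bound()` returns the consistent bound as
  the operative value and the variant alongside for reference.
* **Metric guard.** The predictions assume normalized L1. Internal
  comparison helpers refuse matrices tagged with another metric rather
  than silently applying the formulas.

The nearest-neighbor formula is itself a crude approximation: at moderate
dimensionality it overshoots the simulated mean first-neighbor distance by
up to roughly a third (the test suite bounds the relative error at 35 %
over $N \in \{50, 200, 1000\}$, $D \in \{2, 5, 10\}$), and the error
shrinks monotonically as $D$ grows — to a few percent by $D \sim 1000$,
which is the distance-concentration regime the shrinkage analysis actually
relies on. The asymptote tests operate there.

## What the generators emulate

`sim_gaussian_clusters()` draws cluster centers uniformly in the unit
hypercube and isotropic Gaussian points around them (default sd 0.1 —
clusters an order of magnitude tighter than the unit cube).
`sim_uniform_noise()` fills the same hypercube uniformly;
`sim_noisy_gaussians()` combines the two from one master seed with
independent sub-streams, so changing the noise count never changes the
cluster draw. `sim_theory_scenario()` is the idealized variant with
exactly coincident cluster points. The center law is a package choice: the
idealized analysis states uniform centers, and we use the same law for the
Gaussian benchmark for consistency.

These generators emulate the *structure* assumed by the analysis — tight
isotropic clusters plus uniform background — and nothing else. Real data
have anisotropic, unevenly sized, possibly overlapping clusters, noise
that is structured rather than uniform, and metrics that are only
approximately Euclidean. Passing tests on these generators therefore
demonstrates correctness of the transform and of the predicted shrinkage
mechanics, not performance on any particular real data set.

`measure_shrinkage()` reports, per pair type, the mean original distance
$\bar d$, mean transformed $\bar f$, absolute shrinkage
$\Delta = \bar d - \bar f$ and retained fraction $\bar f / \bar d$.
"Cluster-cluster" means pairs from two *different* clusters; same-cluster
pairs are a separate diagnostic type (`include_within = TRUE`). With
coincident clusters and $k$ below the cluster size,
$\Delta(\text{cluster-cluster})$ is exactly zero — every reference
neighbor of a cluster point is a coincident duplicate, so each term
reproduces $d_{i,j}$.

## Evaluation harness choices

* **Embedding.** `embed_2d()` delegates to Rtsne (Barnes–Hut t-SNE) on the
  precomputed matrix, single-threaded and seeded so identical inputs give
  identical coordinates; perplexity defaults to 30. UMAP (via uwot) is a
  pass-through option.
* **K-means.** `cluster_and_score()` uses `stats::kmeans` with 10 seeded
  restarts, best within-cluster sum of squares kept. The cluster count
  defaults to the number of true clusters **plus one**, so the noise group
  can claim its own cluster; ground truth places all noise in a single
  class. A degenerate (all-identical) embedding scores ARI 0 with a
  warning.
* **KNN on dissimilarities.** `knn_cv_score()` is a hand-written
  K-nearest-neighbor classifier operating directly on the dissimilarity
  matrix (no coordinate representation is assumed), with stratified seeded
  folds (default 5); the neighbor count is selected from a grid by
  cross-validated accuracy, ties to the smaller count, prediction ties to
  the class with smaller summed neighbor distance.
* **Noise detector.** `detect_noise()` flags points whose $K$-NN set
  overlap before vs. after the transform falls below a threshold (default
  0.65). The overlap neighborhood defaults, in the experiment driver, to
  the *cluster size* rather than the transform's `k`: below the cluster
  size the overlap mostly measures harmless intra-cluster rank
  reshuffling (the transform reorders near-equal within-cluster
  distances), whereas at the cluster-size scale it measures genuine
  neighborhood-identity change, which is the signal that separates noise
  from cluster points.
* **Stochasticity policy.** Every stochastic claim in the tests is
  evaluated as a mean over ten or more master seeds (two to five for the
  expensive high-dimensional asymptote checks, whose across-seed variance
  is tiny); one master seed derives all component sub-streams.

## Known limitations

* The transform needs the full $N \times N$ matrix; this implementation
  makes no attempt at approximate neighbors or out-of-core operation.
* The closed forms are asymptotic idealizations; at moderate $D$ and large
  noise counts the noise group shrinks only partially
  ($\bar f / \bar d \approx 1 - (1/N)^{1/D}$-scaled), and a subsequent
  K-means on the embedding may still split the (large-area) noise group
  rather than merge two genuine clusters — inertia scales with group size.
  In the packaged benchmarks this matters at 500 noise points in $D = 20$:
  the noise group separates visually but K-means with best-inertia
  restarts splits it, capping the post-transform ARI well below the
  small-noise regime, where the same pipeline reaches ARI 1.0 (see the
  acceptance tests for both sizes). The unsupervised detector
  (`detect_noise()`), which does not depend on K-means, is the robust
  route at such sizes.
* Problem sizes in the test suite (chosen to keep the full suite
  comfortably interactive): oracle cross-checks at $N \le 50$; embedding
  checks at $N \le 600$; asymptote checks at $D \le 5000$ with 300 points;
  shrinkage grids up to 4096 noise points.
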
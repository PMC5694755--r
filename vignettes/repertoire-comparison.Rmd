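---
title: "Sequence-based comparison of TCR repertoires in low dimensions"
author: "recold package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based comparison of TCR repertoires in low dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recold)
```

## The problem

Two T-cell receptor (TCR) repertoires rarely share many identical CDR3
sequences: the potential sequence space exceeds $10^{15}$, so even deeply
sequenced samples cover it sparsely. Count-based comparisons — the
Bray–Curtis index, Poisson-abundance models — see only the sequences that
happen to overlap (or their abundance spectra) and therefore break down
exactly where the interesting biology lives: in highly diverse repertoires
with almost no overlap. They also cannot say *which* sequences make two
repertoires different.

`recold` compares repertoires through the sequences themselves. Similar but
non-identical CDR3s count as evidence of similarity, graded by an amino-acid
substitution matrix, and the sequences driving a pairwise difference fall
out of the analysis as a by-product.

## The five stages

**1. Alignment dissimilarity.** Every pair among the $N$ unique CDR3 amino
acid sequences pooled over all samples is scored by Smith–Waterman local
alignment with affine gaps (defaults: BLOSUM62, gap open 10, gap extend 1;
a gap of length $L$ costs $\mathrm{open} + (L-1)\cdot\mathrm{extend}$, the
convention of the striped-SW/parasail family of aligners, with the
alternative $\mathrm{open} + L\cdot\mathrm{extend}$ available as a toggle).
Because the self-alignment score grows with sequence length, raw scores
conflate similarity with length. The length-adjusted dissimilarity

$$S_{ij} = 1 - \frac{2\,D_{ij}}{D_{ii} + D_{jj}}$$

removes this effect: identical sequences map to 0, pairs with no
positively-scoring local alignment map to 1, and a sequence is no longer
"similar" to its own tandem duplication for free. All ten standard NCBI
score tables (PAM 30/100/120/160/250, BLOSUM 45/50/62/80/100) are bundled
as pinned plain-text copies so results do not drift with external data
files. BLOSUM62 is the default because it is the field's standard choice
for TCR and antigen-peptide work and sits in the middle of the
cluster-resolution trade-off the matrix families span.

**2. Embedding.** $S$ is not Euclidean and the sequence space has no
coordinates, so the matrix is embedded into $d$ dimensions (default 2) by
one of four methods that need only pairwise dissimilarities:

* **MDS (SMACOF)** minimizes the raw stress
  $\sum_{i<j}(S_{ij} - \lVert y_i - y_j\rVert)^2$ by iterative
  majorization; each Guttman transform provably does not increase the
  stress, which the tests assert. Initialization is classical (Torgerson)
  scaling, so the result is deterministic up to rigid motion.
* **ISOMAP** replaces $S$ with geodesic distances along the union-
  symmetrized k-nearest-neighbour graph (Floyd–Warshall all-pairs shortest
  paths) before the same stress minimization. A disconnected graph is an
  error that reports the component count rather than silently embedding
  fragments.
* **Spectral embedding** (Laplacian eigenmaps) uses the eigenvectors of
  the symmetric normalized Laplacian of the kNN adjacency (unit weights)
  for the $d$ smallest nonzero eigenvalues; eigenvector signs are fixed
  deterministically.
* **t-SNE** calibrates per-point Gaussian bandwidths on the squared
  dissimilarities to a target perplexity (default 30), then minimizes the
  KL divergence to a Student-t kernel layout by gradient descent with
  momentum and early exaggeration, with the learning rate set by the
  $\max(N/48, 50)$ heuristic.

Defaults: `k_neighbors = 10` for the graph methods and perplexity 30 —
conventional values for data sets of a few hundred to a few thousand
points; both are exposed in the configuration. MDS is the pipeline default
because it is deterministic and spreads points widely; t-SNE is the better
choice when the goal is *identifying contributing sequences*, because its
heavy-tailed embedded-space kernel contracts motif families into compact,
well-separated blobs, so the top local-divergence bins coincide with
sequence-occupied regions instead of a smoothed halo. Only inter-point
distances are meaningful in any of these embeddings; no test or analysis in
the package ever asserts absolute coordinates.

**3. Density estimation.** The embedded space is discretized into a shared
grid (default 400 bins per axis) spanning, on each axis,
$[\min x - (\max x - \min x)/10,\ \max x + (\max x - \min x)/10]$ computed
over **all** samples' points, so every sample's density lives on identical
support. Each sample's distribution is an exponential-kernel KDE evaluated
at bin centres,
$p(c) \propto \sum_j w_j \exp(-\lVert c - y_j\rVert / h)$, normalized
discretely so the bin probabilities sum to 1 (making the divergence below
an exact finite sum). Weights default to 1 per unique sequence; setting
them to the clone read counts gives the count-weighted variant. The
bandwidth $h$ is chosen per sample by maximum-likelihood cross-validation
(default 5 folds) over a log-spaced ladder spanning $[10^{-2}, 10]$ times
the sample's median nearest-neighbour distance; per-sample optimization is
used because each density is per-sample, and a global override is
available. Bin membership uses half-open intervals with the last bin
closed, so assignment is deterministic.

**4. Divergence.** Pairwise repertoire difference is the Jensen–Shannon
divergence on the discretized densities,

$$D_{JS}[P\Vert Q] = \sum_x \tfrac12\left\{P(x)\ln\frac{P(x)}{M(x)} +
Q(x)\ln\frac{Q(x)}{M(x)}\right\}, \qquad M = \tfrac{P+Q}{2},$$

in natural-log units (range $[0, \ln 2]$; a bits option divides by
$\ln 2$), with the continuity convention $0\ln 0 = 0$. The per-bin summand
is the **local JSD**; it sums exactly to the global value, and its largest
bins mark the regions of embedded space where the two repertoires disagree.
The sequences of either sample falling in the top 1% of
positive-local-JSD bins (ties at the cutoff included) are reported as the
*contributing sequences* of that pair. The denominator is the number of
bins with positive local JSD, not the full grid: with an
infinite-support kernel the far field carries positive but negligible
divergence, and counting it would only rescale the fraction.

Significance is assessed per sample by a bootstrap of the estimated
density: `n_boot = 100` replicates resample points from the density's
discrete bin distribution (uniformly jittered within the bin, so the
re-estimated KDE never sees coincident points), re-estimate the density
with the same grid and bandwidth, and record the JSD between naive and
re-estimated densities. The number of resampled points matches the
estimator being bootstrapped: one point per unique sequence for the
default unweighted KDE, one per read for the count-weighted variant —
resampling more points than the estimator used would understate its
sampling noise and flag biological replicates as different. The 99th percentile of these
sampling-noise JSDs (linear interpolation between order statistics) is the
one-sided 99% threshold. A pair is flagged significant when its naive JSD
exceeds the thresholds of **both** of its samples — the conservative
combination of the two per-sample nulls. The bootstrap reuses the naive
bandwidth rather than re-optimizing per replicate: the null being simulated
is sampling noise around the *estimated* density, and re-optimization would
multiply the cost a hundredfold.

**5. Clustering.** The pairwise JSD matrix is agglomerated with Ward's
criterion (Lance–Williams update applied to the matrix as-is). JSD is not a
squared-Euclidean distance, so Ward is a heuristic here — the same
heuristic practitioners apply to such matrices — and average/complete
linkage are options. The cophenetic correlation is provided as a
diagnostic, but the bootstrap test above is the preferred statement of
which merges are meaningful, since the dendrogram will happily draw
structure of any strength.

## The synthetic study designs

Real benchmark repertoires require controlled-access downloads, so the
package ships a generator whose designs play the role of study conditions.

A **motif family** is a consensus CDR3 template (length 11–16, conserved
C-prefix and F/W-bearing suffix, mirroring CDR3 anatomy) with designated
variable positions; sequences substitute random residues at those positions
and occasionally gain or lose one residue. Each family materializes a pool
of distinct sequences; samples draw from the pools without replacement, so
samples sharing a family overlap partially (pool size is twice the largest
per-sample demand). Clone counts follow a discrete power law (exponent 2.5,
the heavy-tailed regime typical of clone-size distributions), which gives
the count-weighted KDE and the depth-equalization path realistic input.

The **planted-difference design** gives one sample a 20% admixture from a
tight exclusive family (two variable positions, substitution rate 0.4)
over a diverse shared base family (five variable positions, substitution
rate 0.8, indel probability 0.2), plus two exchangeable base-only samples.
The tight/diffuse contrast is the fixture's point: the exclusive family
forms a compact cluster that the local JSD should flag, while the shared
base region contributes nothing. The **hierarchical design** crosses two
"genetic backgrounds" (different conserved suffixes — large divergence) with
two "cell types" (different central consensus — moderate) and two "donor
sites" (same family pool, different draw — sampling-level divergence),
eight samples whose planted partition a Ward cut at 2 and 4 clusters should
recover.

What the generator does *not* emulate: V(D)J recombination statistics,
PCR amplification bias, sequencing error, and the germline-gene-driven
correlation structure of real CDR3s. Passing tests therefore demonstrate
that the pipeline's machinery — scoring, embedding, estimation, inference —
behaves as specified on data with known ground truth, not that any
particular biological conclusion transfers to a given real data set.

## Numerical choices and problem sizes

* The synthetic studies in the tests and the acceptance script use 200
  unique sequences per sample (about 500 reads at the power-law counts),
  100 bins per axis, and 100 bootstrap replicates; the hierarchy study uses
  eight samples of 120 unique sequences. These sizes exercise every code
  path at full statistical settings while a complete study runs in tens of
  seconds. The 400-bin default matches the method's standard resolution for
  real data sets; divergences change only marginally between 100 and 400
  bins because both densities are smoothed by the same kernel.
* Kernel sums are computed by a compiled double loop; a plain-R
  implementation is kept as the reference and the two are required to agree
  to $10^{-9}$ relative error.
* SMACOF stops when the stress decrease falls below $10^{-9}$ relative or
  at `max_iter` (default 300). t-SNE runs a fixed iteration budget
  (default 1000) with exaggeration 12 for the first 100 iterations.
* Degenerate inputs fail loudly: empty repertoires, non-canonical residues,
  all-identical coordinates on an axis, disconnected kNN graphs, zero
  self-alignment scores, and constant distance vectors for the cophenetic
  correlation are all errors, not warnings.
* Equal local-JSD values at the top-1% cutoff are all included, so the
  reported bin set does not depend on sort stability.

## A worked example

```{r example, eval = FALSE}
library(recold)

base <- motif_family("CAASAYQLIWG", variable = 2:6, sub_rate = 0.8,
                     indel_prob = 0.2, name = "base")
excl <- motif_family("CAASNTGGLSGKLTFG", variable = c(5, 7), sub_rate = 0.4,
                     indel_prob = 0, name = "excl")
design <- planted_difference_design(base, excl, exclusivity = 0.2,
                                    n_unique = 200, seed = 101)
reps <- generate_repertoires(design)

cfg <- pipeline_config(method = "tsne", bins = 100, n_boot = 100, seed = 1)
res <- run_pipeline(reps, cfg, out_dir = "recold_out")

round(res$jsd, 4)          # pairwise-sample JSD matrix
res$significant            # bootstrap significance flags
res$contributing[["planted__base1"]]   # sequences driving the difference
plot(res$dendrogram)
```

On this design the planted-vs-base JSD is an order of magnitude above the
base-vs-base JSD, the bootstrap flags only the planted pairs, and the
contributing set for the planted sample consists almost entirely of the
exclusive-family sequences. The per-length position-frequency matrix of
those sequences (`position_frequency_matrix`) exposes the planted
consensus — the numeric content of a sequence logo.

## Known limitations

* The all-pairs alignment stage is quadratic in the number of unique
  sequences; beyond a few tens of thousands of sequences it dominates the
  runtime, and subsampling (`equalize_read_depth`) is the intended
  mitigation, as it also removes depth bias.
* Embeddings are only defined up to rigid motion, and t-SNE additionally
  depends on its seed; divergences computed downstream inherit a mild
  seed dependence that the bootstrap test is designed to dominate.
* Ward linkage on a JSD matrix is a heuristic (see above).
* KDE grids are supported in 1 or 2 dimensions; higher-dimensional
  embeddings would need a different density representation than a dense
  per-bin grid.
* No multiple-testing correction is applied across sample pairs; the
  bootstrap threshold is per pair.
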
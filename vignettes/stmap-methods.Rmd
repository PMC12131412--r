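---
title: "Mapping transcriptomes to spatial coordinates: models and methods"
author: "stmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptomes to spatial coordinates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmap)
```

## The problem

Sequencing-based spatial transcriptomics (ST) assays - Visium spots,
Slide-seqV2 beads, Stereo-seq voxels - measure a transcriptome at every
capture unit together with its position in the tissue. Single-cell RNA-seq
measures richer transcriptomes but discards position. `stmap` treats the
link between the two as a regression problem: *the transcriptome of a cell
predicts where it sits*. A network trained on reference ST data maps query
transcriptomes (held-out spots, or scRNA-seq cells) to tissue coordinates,
reconstructs bead-level expression from the cells that land near each bead,
and - by reading the trained weights backwards - ranks the genes that carry
the positional signal, a weight-space route to spatially variable genes
(SVGs).

## The model

Counts are library-size normalized to 10,000 per observation and
transformed with $\ln(1+x)$ (`normalize_counts()`). Spatial coordinates are
min-max normalized per axis to $[0,1]$ (`fit_coord_normalizer()`); a polar
option converts 2D positions to (radius, angle) about the centroid first,
which suits roughly circular tissues. Angles are measured in radians in
$(-\pi, \pi]$ and both polar axes get the same min-max treatment - the
choice is uniform because nothing in the problem distinguishes the axes
once they are targets.

The regressor is a fully connected network
$$\hat{y} = \sigma\!\left(W_L\,\mathrm{ReLU}(\cdots \mathrm{ReLU}(W_1 x + b_1) \cdots) + b_L\right),$$
with ReLU hidden activations and a sigmoid output so predictions live in
$(0,1)^d$ like the targets. The reference architecture has six hidden
layers of 4096, 1024, 256, 64, 16 and 4 nodes. The training loss is the
root-mean-square coordinate error plus an L1 penalty on all weight
matrices (biases excluded),
$$\mathcal{L} = \sqrt{\tfrac{1}{N}\sum_t \lVert y_t - \hat{y}_t\rVert^2}
  + \lambda \sum_{i,j,k} |W_{ijk}|, \qquad \lambda = 10^{-8},$$
minimized by Adam at learning rate 0.001 (moments 0.9/0.999, epsilon
1e-7). Weights start from the Glorot normal distribution; biases start at
zero. Dropout at rate 0.05 is applied to the input and the first five
hidden layers, after the activation, during training only; an opt-in
Monte-Carlo dropout mode (`predict(..., mc_dropout = TRUE)`) averages
stochastic forward passes for users who want prediction-time perturbation.
The learning rate is halved after 20 epochs without validation improvement
down to 1e-5, and training stops after 50 epochs without improvement or at
the epoch cap (500 by default). A seeded random 10% of the reference is
held out as the validation split; no batch or layer normalization is used
anywhere. Early stopping restores the weights of the best-validation
epoch: the held-out correlation $\bar{r}$ reported by the model (and used
to scale importance scores below) presumes the returned weights are the
ones that achieved it.

Batch sizes should scale with the data: 16-128 for datasets of a few
hundred to a few thousand observations (Visium scale), 4096 for larger
bead-level assays. `train_config()` defaults to 4096 and clamps, with a
warning, when the training set is smaller.

### Initialization sensitivity and restarts

A deep rectifier stack that narrows to 4 nodes can start on a plateau
where every input maps to the mean coordinate; most initializations escape
within a few epochs, but occasionally the plateau outlasts the
early-stopping patience, or only one output axis escapes, and the run
returns a degenerate fit. Converged and stuck runs are well separated in
practice: a converged run ends with a validation loss around a fifth of
its starting value, a stuck or half-stuck one above 70% of it. When the
best validation loss fails to at least halve its starting value, or any
output axis shows near-zero validation correlation, `train_model()`
re-initializes with a seed derived deterministically from the configured
seed (up to `restarts = 2` extra attempts) and returns the attempt with
the lowest validation loss. Everything stays bit-for-bit reproducible for
a fixed seed.

## Gene filtering across batches

When reference and query come from different assays, genes whose
expression distributions disagree mostly add noise. For each gene shared
by both datasets the 1D Wasserstein distance
$W_1(u,v) = \int |U - V|\,dx$ between the empirical distributions of its
normalized expression is computed by exact step-function integration on
the merged support, with equal mass $1/n$ per observation - no resampling,
any pair of sample sizes. Genes with $W_1 < 0.1$ are kept
(`select_genes()`); a constant batch shift of size $c$ moves $W_1$ by
exactly $|c|$, which is what makes the threshold interpretable. Distances
are computed on the normalized log scale, matching the pipeline order
(selection happens after normalization). When no query set exists -
cross-validation within one ST dataset - filtering is skipped and all
genes are used.

## Fine mapping and reconstruction

Predicted unit-interval coordinates are denormalized with the reference
normalizer before any distance is computed, so cutoffs are in the tissue's
units (micrometres for the assays above). Each reference bead collects the
cells within `cutoff` of its center - 15 um is the natural radius for
Slide-seqV2-like data, 110 um for Visium-like; both values are treated as
radii. Cell $j$ of the $k$ members gets weight
$$w_j = \frac{1/d_j}{\sum_{i=1}^{k} 1/d_i},$$
and the bead's reconstructed expression is $\sum_j w_j\,x_j$, a convex
combination. A cell exactly at the center ($d=0$) takes the limit: the
zero-distance cells share all the mass. Cells may serve several beads;
beads with no cells are returned as missing (`NA`), never as zeros, so
downstream statistics skip them instead of being dragged toward zero.

Consistency between reconstruction and reference is quantified per gene by
bivariate Moran's I over a spatial weights graph with
$w_{ij} = 100/d_{ij}$ for pairs closer than a threshold and 0 otherwise.
The threshold has no published value; the default is twice the 95th
percentile of nearest-neighbour distances - wide enough to connect every
spot to a ring of neighbours, narrow enough to stay local - and it is
logged on every use. Per-gene Moran's I for the SVG comparison instead
uses symmetric binary k-nearest-neighbour weights with $k=6$, the common
default of spatial single-cell toolkits.

## Weight backtracking for SVGs

The importance of gene $j$ is accumulated backwards through the weight
matrices. For the last matrix $S_{I,j} = \sum_k |W_{I,j,k}|$; for every
earlier matrix only the columns whose downstream score exceeds the
median (the $r$-th percentile, $r = 50$) contribute:
$$S_{i,j} = \sum_k \mathbf{1}\!\left[S_{i+1,k} > \mathrm{Percentile}(S_{i+1}, r)\right] |W_{i,j,k}|.$$
The unmasked base case is applied to the *last* matrix and the masked
recursion to earlier ones: the backward pass starts at the output and the
returned scores are $S_1$, so masking must act on the layers between.
Percentiles use linear interpolation between order statistics
(`stats::quantile` type 7); the comparison is strict, and zero scores are
not excluded from the percentile. Raw scores are normalized to
$$S^{\mathrm{norm}}_{1,j} = \frac{S_{1,j}}{\sum_i S_{1,i}}\,\bar{r}\cdot\mathrm{Scaler},
  \qquad \mathrm{Scaler} = 1000,$$
so scores from a badly fit model ($\bar{r}\approx 0$) shrink toward zero
and totals are comparable across tissues. Ties in the final ranking break
lexicographically by gene id, which keeps output deterministic.

A single trained network is a noisy measurement of gene importance; when a
cross-validation has been run anyway, `cv_importance_scores()` averages
the scores over the fold models, which stabilizes the ranking at no extra
training cost and is the recommended basis for calling SVGs.

## Benchmarking metrics

Absolute predicted positions are less meaningful than preserved geometry -
a mapping that rigidly rotates the tissue is perfect for every practical
purpose. Accuracy is therefore scored on *pairwise distances*: the Pearson
correlation and the RMSE between the vector of all intercellular distances
of the true and of the predicted coordinates, under a canonical $i<j$ pair
ordering. Both metrics are exactly invariant to rigid motions of either
point set because only distances enter. Following the benchmarking
convention, `crossvalidate()` computes them on min-max normalized
coordinates (the fold normalizer's unit space), so RMSE is a fraction of
the tissue extent. Fivefold cross-validation partitions observations with
a seeded shuffle; per-fold and pooled metrics are both reported because
the two summaries answer slightly different questions (typical fold
performance vs whole-map performance). An optional bootstrap resamples the
pooled left-out spots (200 replicates by convention) for error bars;
duplicated resampled spots are dropped within a replicate because
duplicate positions create zero distances. `permuted_baseline()` destroys
the cell-position correspondence by permutation and reports the median
metric over permutations - the floor any real mapping must beat.

## The synthetic generator

`generate_reference()` emulates the features of sequencing-based ST that
matter to this pipeline and nothing else: spots in a square tissue
(uniform, grid, or annulus layouts; 1 mm box by default), a minority of
genes whose expected expression follows a smooth spatial surface (linear
gradients, Gaussian bumps, concentric rings, half-plane steps), flat noise
genes, and negative-binomial counts (dispersion `size = 10`) with
lognormal per-spot depth factors (sdlog 0.3, mean-one) around a mean depth
of 2,000 UMIs - overdispersion and depth variation being the two count
pathologies the normalization must absorb. Gene base abundances are
lognormal; every pattern surface is rescaled to a common 16-fold dynamic
range so that SVG difficulty is controlled by depth and dispersion rather
than amplitude. The default study size (1,500 spots, 150 genes, 40 SVGs)
keeps a full fivefold cross-validation with a [256, 64, 16, 4] network and
a 150-epoch cap around a minute on one CPU while leaving each fold enough
data to fit.

`generate_query()` places new cells in the same tissue under the same
surfaces, and returns expression already normalized and log-transformed,
with an optional constant batch shift added *on that scale* to a recorded
subset of genes - on the normalized scale because that is where the
Wasserstein filter's translation property is exact. True query positions
are recorded in the ground truth but withheld from the dataset itself, so
they cannot leak into training.

What passing tests on this generator do **not** show: robustness to
segmentation errors, doublets, ambient RNA, cell-type composition shifts
between reference and query, or spatial patterns at scales below the
spot spacing. Real-data behaviour must be judged on real data; the
generator establishes correctness of the machinery and recoverability
under controlled noise.

## Numerical choices and degenerate inputs

* Normalize-then-denormalize round-trips are exact to 1e-9; a coordinate
  axis with zero range is an error, not a silent division by zero.
* Out-of-range query predictions are *not* clipped by the normalizer;
  whether to clip belongs to mapping policy, and the mapping module simply
  lets far-out predictions match no bead (they are counted in a log line).
* Constant expression vectors make Moran's I and its bivariate form
  undefined; both raise typed errors rather than returning 0, because a
  silent 0 would corrupt SVG rankings.
* The RMSE gradient divides by the current loss value; at an exactly zero
  residual the gradient is defined as zero.
* Mini-batch order is reshuffled each epoch from the seeded stream;
  training is bit-for-bit reproducible in single-threaded BLAS.
* All derived seeds (folds, restarts, bootstrap) come from one root seed
  through a fixed integer map, and stay inside the 32-bit range R
  requires.

## Limitations

The mapper assumes the query tissue is the reference tissue: it places
cells on the trained coordinate range and cannot extrapolate to unseen
anatomy. Importance scores have no null model - they rank genes but do not
test them; treat the ranking as a screen. The 100/d weight scheme is
undefined at duplicate positions, which are rejected. Training on datasets
far larger than ~10^5 observations is possible but not tuned for; the
implementation is plain BLAS matrix arithmetic, adequate for the spot
counts of current assays on a laptop CPU.
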
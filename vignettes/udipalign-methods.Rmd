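---
title: "Multimodal momentum-contrast imaging phenotypes: models and methods"
author: "UDIPalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal momentum-contrast imaging phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Paired volumetric images of the same subject in two modalities (for brain
MRI: T1- and T2-weighted scans registered to a common space) carry both
shared anatomical structure and modality-specific contrast. This package
learns a *shared* representation by self-supervised contrastive training in
which the two modality renderings of one subject are a positive pair and all
other combinations are negatives. The frozen encoder then turns each scan
into a compact vector of latent imaging phenotypes (UDIPs:
unsupervised-learning-derived imaging phenotypes), which are treated as
quantitative traits: cross-modal alignment is quantified at the feature
level (linear CKA, CCA) and at the genetic level (association scans, minP
aggregation, locus clumping and padded locus overlap between the
per-modality scans).

# The contrastive core

## Architecture

Each volume is zero-padded symmetrically (extra voxel on the high side of an
odd remainder) to a shape divisible by the patch size, tiled into
non-overlapping patches in x-fastest order, and encoded by a ViT: linear
patch projection, learned positional encoding, `depth` pre-norm transformer
blocks (multi-head self-attention, GELU MLP), final LayerNorm. The
instance-level representation is the mean over patch embeddings; a 2-layer
ReLU projection head maps it to the contrastive space where vectors are
L2-normalized.

Two pooling conventions are defensible (class token vs mean pooling, and
whether the head sees pooled or per-patch tokens); the package pools by
patch mean before the head because instance discrimination operates on one
vector per volume, and the per-patch embeddings remain available pre-pooling
for extraction. This choice is recorded here because the alternative is
equally legitimate.

## Objective and optimization

One query encoder and one momentum ("key") encoder are shared across
modalities; fusion arises purely from parameter sharing. For a batch of
paired volumes the symmetric objective is

$$L = \tfrac12\big(L_{a\to b} + L_{b\to a}\big),\qquad
L_{q\to k} = -\log\frac{e^{q\cdot k^+/\tau}}
{e^{q\cdot k^+/\tau} + \sum_{j=1}^{K} e^{q\cdot k^-_j/\tau}}$$

with temperature $\tau$ and $K$ negatives drawn from a FIFO queue of past
key embeddings. Gradients flow through the query encoder only; the key
encoder follows as an exponential moving average
$\theta_k \leftarrow m\,\theta_k + (1-m)\,\theta_q$, and each step's key
embeddings are enqueued, evicting the $B$ oldest entries.

Two design points the loss formulation leaves open:

* **Queue composition.** The package keeps one queue per modality and draws
  negatives from the queue of the *current key's* modality. With a single
  mixed queue the loss can be partially solved by discriminating modalities
  instead of subjects; per-modality queues remove that shortcut.
* **Queue initialization.** Queues are pre-filled with random unit vectors
  so the loss is well-defined from step 1. Both queues start from the same
  draw, which makes the symmetric objective an exact symmetry of the fresh
  state (they diverge as soon as real keys are enqueued).

Optimization is AdamW (decoupled weight decay 0.01) under a
cosine-annealing warm-restart schedule $(T_0, T_{mult}, \eta_{min})$.
All arithmetic is double precision — R's native numeric — with log-sum-exp
stabilization in every softmax; gradients are computed by a hand-written
reverse pass (compiled kernel, with a base-R reference implementation
cross-checked in the test suite and verified against finite differences).

## Parameters and defaults

| parameter | default | notes |
|---|---|---|
| temperature $\tau$ | 0.07 | similarity scale of the softmax |
| momentum $m$ | 0.999 | key-encoder EMA coefficient |
| queue size $K$ | 65,536 | full-scale; desk profile 1,024 |
| learning rate | 1e-4 | full-scale AdamW; desk profile 1e-3 |
| schedule | $T_0{=}10$, $T_{mult}{=}2$, $\eta_{min}{=}10^{-6}$ | warm restarts |
| epochs | 300 | full-scale; desk profile 20 |
| encoder | 12 layers, 6 heads, width 384, proj 256 | full-scale |
| desk encoder | 2 layers, 4 heads, width 64, proj 32, MLP ratio 2 | |
| patch size | 14×16×14 on 182×224×182 | desk: 8×8×8 on 32³ |

The full-scale patch size is not uniquely determined by a patch *count*
alone; 14×16×14 is adopted because it is the near-isotropic factorization of
182×224×182 that yields a 13×14×13 grid of exactly 2,366 patches. The desk
profile (returned by `deskEncoderConfig()` / `deskContrastiveConfig()`) uses
a batch size of 50 and a learning rate of 1e-3 so that 20 epochs on a
200-subject cohort make visible training progress; the full-scale profile is
recorded in `fullScaleProfile()` but is far beyond desktop compute.

# From embeddings to UDIPs

`extractEmbeddings()` applies the frozen query encoder without the
projection head, giving a subjects × patches × width tensor per modality.
Each subject's patch matrix is flattened patch-major (feature
$(p-1)\cdot\text{width}+w$; the order is fixed and documented so saved PCA
bases are portable) and reduced by PCA. The default is a *joint* fit: one
basis estimated on the stacked rows of both modalities (column-mean
centering only, no variance scaling), then both modalities projected with
it, which places them in a single coordinate system — identical inputs from
the two streams get identical UDIPs. A per-modality fit is available
(`jointFit = FALSE`) since the joint convention is itself a modelling
choice.

Outlier QC masks, per UDIP column, entries strictly more than `zThresh`
(default 5) SDs from the column mean. Statistics are computed once on the
unmasked values, so masking is idempotent; masking is per-entry, so each
UDIP's downstream sample size can differ.

# Alignment metrics

*Linear CKA* is computed in its feature-space form
$\|Y_c^\top X_c\|_F^2 / (\|X_c^\top X_c\|_F\,\|Y_c^\top Y_c\|_F)$ with the
standard (biased) HSIC estimator — equal to the cosine similarity of the
centered Gram matrices, invariant to rotation, translation and positive
rescaling, bounded in $[0,1]$. Positive-pair uncertainty comes from
bootstrap resampling of matched rows; the negative distribution uses random
permutations of the modality-b assignment, redrawn until no fixed point
remains so that no true pair leaks into the null. One caveat the package's
tests make explicit: bootstrap duplication of rows inflates CKA slightly
even under independence, so the bootstrap and permutation nulls have a
small systematic gap (~0.02 at n = 300) that shrinks with sample size —
irrelevant next to real alignment signals but visible in null simulations.

*CCA* standardizes both blocks, removes incomplete rows, and computes
canonical correlations with the number of components
$\min(n-1, \min(p, q))$. No regularization is applied; a warning fires when
$n < 5\max(p,q)$ because unregularized in-sample correlations inflate.
Summaries: mean, max, counts of $\rho$ strictly above 0.3 and 0.5, and the
normalized area under the sorted-$\rho$ profile (equal to the mean).

# The genetics miniature

The association scan is OLS: per UDIP, phenotype and dosages are
residualized on the covariates (intercept included) and the residual simple
regression is computed — numerically identical to the SNP coefficient of
the full multiple regression by Frisch–Waugh, with two-sided p-values on
$n - c - 2$ degrees of freedom. A linear mixed model is deliberately *not*
used: the synthetic subjects are unrelated Hardy–Weinberg draws, so the
random effect a tool like a mixed-model GWAS adds for relatedness would be
inert here. SNPs below the MAF threshold (default 0.01) are dropped;
constant-dosage SNPs are skipped with a warning.

Per SNP, minP aggregation takes the minimum p over UDIPs (ties to the
lowest UDIP index). Clumping is a single-tier surrogate of the usual
two-tier LD scheme: significant SNPs (minP < $5\times10^{-8}/128$ by
default) sorted by ascending minP (ties by position, then SNP id); the best
remaining SNP leads a locus and absorbs all remaining same-chromosome
significant SNPs with dosage $r^2 > 0.1$; loci closer than 250 kb merge,
the merged lead being the member with smallest minP. Coordinates are
1-based inclusive internally; BED export converts to 0-based half-open.

For overlap, every locus is extended by 125 kb on both sides (floored at
position 1, no chromosome-length ceiling since synthetic chromosomes are
unbounded) and the extended loci of both sets are clustered by transitive
interval intersection per chromosome, implemented on GenomicRanges/IRanges
interval indexing and verified against an all-pairs union-find oracle. A
cluster with members from both sets is shared;
shared + uniqueA + uniqueB = total always holds, and the shared percentage
is 100·shared/total (defined as 0 for two empty sets). "Total" counts
union-clusters — with shared loci counted once — which is the convention
consistent with partitions like 23 shared out of 44. Novel loci are target
loci whose padded interval meets no padded reference locus.

# Phenotype associations

`phewasScan()` fits trait ~ UDIP + covariates per pair, with
pairwise-complete handling of masked entries and a Bonferroni threshold
0.05/(#UDIPs × #traits) computed from the actual dimensions. Covariates
enter each regression directly (equivalent to pre-residualization by
Frisch–Waugh). P-values are floored at 1e-300 so $-\log_{10}p$ stays
finite. `incrementalR2()` reports $\Delta R^2$ of the UDIP block beyond
covariates with the partial (omnibus) F-test
$F = \frac{(RSS_{red}-RSS_{full})/K}{RSS_{full}/(n-c-K-1)}$; a K = 0 block
is an explicit error. `ccaComponentAssoc()` summarizes, per canonical
component, the 95th percentile of the $-\log_{10}p$ distribution over
traits. The "95th percentile" is read as the strong-association tail of
$-\log_{10}p$ (the reading as the 95th percentile of raw p would summarize
the *weak* tail, which carries no signal and would make the planted-signal
contrast unobservable); `percentile = 100` gives the maximum.

# The synthetic cohort

`simulateCohort()` generates the desk-scale study system, all stages keyed
by subject ID and driven by one master seed that spawns independent
sub-streams (genotypes, latent noise, rendering, traits), so any component
can be regenerated alone:

* **Genotypes**: 2,000 SNPs on 2 chromosomes at 10 kb spacing, allele
  frequencies Uniform(0.05, 0.5), dosages Binomial(2, p) — Hardy–Weinberg,
  unrelated subjects.
* **Latent**: d = 8 dimensions; 8 causal SNPs (one per dimension, evenly
  spaced across the panel, effect 1.0 per SD of dosage) plus N(0, 0.5²)
  noise. Effects of this size give the 200-subject scans realistic power at
  the stringent locus threshold without making every null SNP significant.
* **Volumes**: 32³ voxels; each modality is a fixed random linear map of
  the latent (independent maps per modality), Gaussian-smoothed (σ = 1
  voxel) plus N(0, 0.2²) voxel noise; 5% of voxels carry zero loading as
  pure-noise controls. Setting `sharedLatent = FALSE` renders the first
  half of the latent only into modality a and the second half only into b,
  creating modality-private genetic architecture for overlap-contrast
  experiments while keeping genotypes and latents identical.
* **Traits**: 20 linear read-outs of the latent plus N(0, 0.5²) noise, with
  standardized age and 0/1 sex as covariates.

What this emulates: two modality renderings of one subject-level latent,
pleiotropic causal SNPs, and trait tables that stand in for conventional
IDPs. What it does not: MRI contrast physics, bias fields, registration
artifacts, LD beyond independent draws, population structure or
relatedness. Tests passing on this cohort demonstrate that the machinery
recovers planted structure under its own assumptions — not that the method
meets any particular effect size on real scans.

# Numerical choices and degenerate inputs

* Strict inequalities at every stated threshold ("exceeding 5 SD",
  "$\rho > 0.3$", minP < α); ties at a threshold are not selected.
* Zero-SD UDIP columns: no masking, with a warning. Zero-variance CKA
  input: explicit error (the statistic is undefined). Rank-deficient CCA:
  component count reduced with a warning. Collinear covariates: dropped
  with a warning naming the columns. A (near-)zero vector reaching the
  L2 normalization of the projection head raises an error rather than
  returning NaN.
* Clump tie-breaks: ascending minP, then position, then SNP id, making the
  greedy decomposition deterministic.
* Reproducibility: every stochastic routine takes a seed; training is
  deterministic given its config on a fixed BLAS/thread configuration.

# Problem sizes used by the test and acceptance runs

Unit tests run on toy objects (4³–8³ volumes, ≤ 16 subjects, ≤ 200 SNPs).
The end-to-end recovery checks use the desk conditions: 200 subjects, 32³
volumes, 2,000 SNPs, 8 causal, 20 training epochs, K = 16 UDIPs, repeated
over 5 paired seeds (shared vs modality-private rendering from identical
genotypes). Null calibration uses a 1,000 × 2,000 panel; power uses 20
seeded replicates of a 5%-variance SNP at n = 1,000; incremental-R²
recovery uses n = 5,000. These sizes were chosen so each property is
measured with enough replication to be stable, while a full run of the
suite stays practical on a single workstation core.

# Known limitations

* The OLS scan is valid only for unrelated subjects; no mixed models,
  relatedness correction or population-structure control.
* Clumping is a single-tier LD surrogate, not a reimplementation of
  two-tier fine-mapping pipelines; heritability, genetic correlation and
  functional annotation are out of scope.
* CCA is unregularized and in-sample; at small n relative to feature count
  its correlations inflate (warned).
* The untested plotting conveniences (e.g. bar plots of $\rho$) make no
  quantitative claims.
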
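# UDIPalign

Self-supervised multimodal representation learning for paired volumetric
images, and the downstream machinery for treating the learned
representations as quantitative traits.

**Who it is for.** Imaging-genetics researchers who have paired per-subject
3D scans in two modalities (e.g. T1- and T2-weighted brain MRI registered to
a common space) and want (i) a shared cross-modal embedding learned without
labels, (ii) compact latent imaging phenotypes (UDIPs) derived from it, and
(iii) quantitative answers to "how aligned are the two modalities?" at the
feature level and at the genetic level. A fully synthetic cohort generator
with known ground truth makes every stage testable end to end.

## The model

The core is a symmetric multimodal momentum-contrast framework. The two
modality volumes of one subject form a cross-modal positive pair; negatives
come from per-modality FIFO queues of past key embeddings. With unit-norm
projections $q$ (query) and $k^+$ (key from the paired modality), queue
negatives $k^-_j$ and temperature $\tau$:

$$L = \tfrac12\left(L_{a\to b} + L_{b\to a}\right),\qquad
L_{q\to k}= -\log\frac{e^{q\cdot k^+/\tau}}
{e^{q\cdot k^+/\tau}+\sum_{j=1}^{K}e^{q\cdot k^-_j/\tau}}$$

Both branches share one ViT query encoder (3D patch tokenization, pre-norm
transformer blocks, mean pooling, 2-layer projection head); the key encoder
is its momentum moving average, $\theta_k \leftarrow m\theta_k +
(1-m)\theta_q$. After training the encoder is frozen, the projection head
dropped, and per-patch embeddings are reduced by joint PCA across both
modalities to K UDIPs per modality, with per-entry 5-SD outlier QC.

Downstream: linear CKA with bootstrap/permutation uncertainty, CCA with
canonical-correlation summaries, an OLS association scan over all UDIPs
(covariate-residualized, Frisch–Waugh-exact), per-SNP minP aggregation,
greedy LD/distance clumping into loci ($r^2 \le 0.1$, 250 kb merge),
125 kb-padded interval-tree locus overlap between the per-modality scans,
novel-locus calls against reference sets, and phenome-wide UDIP–trait
association utilities (per-pair regressions, incremental $R^2$ with partial
F omnibus tests, CCA-component association summaries).

## Worked example

Simulate the desk-scale cohort (200 subjects, paired 32³ volumes rendered
from a shared 8-dimensional genetic latent, 2,000 SNPs with 8 planted
causal SNPs), train for 20 epochs, and measure alignment:

```r
library(UDIPalign)

res <- runPipeline(seed = 1L)   # simulate -> train -> embed -> align ->
                                # gwas -> clump -> overlap -> phewas
head(res$training$epochLoss, 3) # 4.919 5.790 5.833
tail(res$training$epochLoss, 3) # 2.901 2.808 2.728
show(res$overlap)
#> OverlapResult: 8 shared / 8 total clusters (100.0% shared); unique A 0, unique B 0

mean(res$align@ckaPos)          # 0.984
mean(res$align@ckaNeg)          # 0.038
S4Vectors::mcols(res$loci$a)$leadSnp
#> "snp00223" "snp00445" "snp00667" "snp00889" "snp01112" "snp01334" ...
```

Reading the numbers: the contrastive loss starts near the theoretical
random-similarity level for a 1,024-entry queue (log 1025 ≈ 6.9, minus the
head start that paired volumes share) and falls as the encoder aligns the
modalities. Matched-subject CKA near 1 against a permutation null near 0
says the two modality embeddings encode the same subjects' structure. The
locus sets from the two modality scans recover the 8 planted causal SNPs
each and coincide — pleiotropy by construction, detected through the full
pipeline. Rendering the latent modality-privately instead
(`cohortArgs = list(sharedLatent = FALSE)`) drops the overlap to 0% while
each modality still finds its own 4 loci.

A thin command-line wrapper for the two shell-friendly entry points lives
at `inst/scripts/udip-pipeline.R` (`simulate`, `run-all`).

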
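---
title: "Staging flower bud dormancy from expression profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging flower bud dormancy from expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budphase)
```

# The biological problem

Temperate fruit trees such as sweet cherry (*Prunus avium*) set their flower
buds in summer and carry them through winter in a dormant state. The cycle
passes through five stages: **organogenesis** (bud formation, July–August),
**paradormancy** (growth cessation imposed by other organs, September),
**endodormancy** (bud-internal dormancy released by chilling accumulation,
from October), **dormancy release** (the transition window), and
**ecodormancy** (inhibition by external conditions only, reversible by
warmth, lasting until flowering). Which stage a bud is in cannot be seen
from the outside; the operational assay is slow — cut branches are forced in
a warm chamber for ten days and the fraction of buds reaching BBCH stage 53
("bud burst") is scored, with dormancy considered released once that
fraction exceeds 50%.

The transcriptome, however, tracks the stages closely. This package
implements a complete analysis chain for seasonal bud RNA-seq time courses
— expression filtering, profile clustering, marker selection, annotation
enrichment — and its end product: a classifier that calls the five stages
from the expression of a small marker panel, cheap enough to run by RT-qPCR
on new samples.

# Pipeline models, stage by stage

## Expression unit and filters

Counts are converted to transcripts per million,
$\mathrm{TPM}_{ij} = \dfrac{c_{ij}/L_i}{\sum_g c_{gj}/L_g} \times 10^6$,
so each sample column sums to $10^6$. Three sequential filters remove genes
that cannot carry temporal signal: mean raw count below 3; zero counts in
more than 75% of samples; coefficient of variation (sd/mean) below 0.3.
Survival therefore requires mean $\ge 3$, zero fraction $\le 0.75$ and CV
$\ge 0.3$. The CV is evaluated on TPM by default — TPM is the unit every
downstream step works in — with raw counts available via `cv_on = "counts"`.

## The differential-expression stand-in

Dormant (endodormancy + dormancy release, by default) versus non-dormant
samples are compared per gene with a Welch $t$-test on $\log_2(\mathrm{TPM}+1)$,
Benjamini–Hochberg adjusted, flagging genes at padj < 0.05. This is an
intentionally transparent stand-in for a count-model DE method, kept behind
an interface that also accepts an externally computed DEG table
(`read_deg_table()`). Two caveats are inherent to any two-group contrast on
a time course and are worth knowing:

* within-group *temporal* spread inflates the denominator of the test, so
  power is far below what the per-replicate noise level would suggest;
* genes whose profile is roughly symmetric across the split (high in summer
  *and* spring, for instance) can have near-equal group means and escape
  detection entirely.

Because of the second point, the pipeline's clustering stage accepts either
the DEG set or all filter survivors (`clustering$gene_set`, default
`"filtered"`); the stand-in's calls are always computed and reported.

## Clustering of temporal profiles

Distances between gene profiles are $d = 1 - r$, with $r$ the Pearson
correlation across the reference cultivar's samples ($d \in [0, 2]$; being
scale- and offset-invariant, TPM and z-score profiles give identical
distances — asserted as a test). Agglomerative clustering with complete
linkage (configurable) is cut into exactly $k = 10$ groups. For display and
ordering, each gene is standardized to a z-score profile,
$z_{ij} = (x_{ij} - \bar{x}_i)/s_i$, using the sample (n−1) standard
deviation; cluster centroids are mean z-scores over member genes and
replicates per timepoint, and clusters are relabeled 1..k by the chronology
of their centroid peak (ties: larger cluster first). Choosing $k$
automatically is out of scope; ten clusters resolve the five stages with
early/late substructure in the longer ones.

## Marker panel

Within each chosen cluster the marker is the gene whose z-profile
correlates best with the cluster centroid, after screening out genes that
would make poor assays: mean TPM below 10 (defaults; "well expressed" is a
qualitative criterion quantified here as a config key), gene families
larger than 5 members (cross-amplification risk), and a user exclusion
list standing in for primer-design failures. Ties break by higher mean
TPM, then lexicographic id. Gene–centroid correlations are computed against
cultivar-resolved centroids (`cultivar_date` timepoints) by default: each
cultivar's own temporal shift is part of the profile being matched, and
averaging cultivars first would blur precisely the genes that track
dormancy best.

## Annotation enrichment

Over-representation of a gene set (TF targets, promoter motifs, GO terms)
in a cluster is the exact hypergeometric upper tail
$P(X \ge k)$ with $X \sim \mathrm{Hyper}(N, K, n)$ — $N$ universe genes,
$K$ annotated, $n$ in the cluster, $k$ annotated in the cluster. The
universe defaults to the clustered (DEG) set, not the genome: the question
asked is "which sets concentrate in this cluster relative to the rest of
the responsive genes". BH correction is applied per cluster × annotation
kind, matching per-cluster reporting; only over-representation is tested.
GO enrichment uses the one-sided Fisher exact test on the 2×2 table (the
identical quantity, implemented as an independent code path and asserted
equal to 1e-12), filtered at raw p < 0.005 and truncated to the ten
smallest p-values. Annotations are taken as flat gene–term tables; no
ontology-graph propagation is performed, so terms should be pre-propagated
upstream if that behavior is wanted.

## The stage classifier

Marker expression is first normalized per cultivar by the October
reference sample (replicate-averaged): October is the start of
endodormancy, is sampled in every cultivar, and — critically — makes the
features unit-free, so RNA-seq TPM and RT-qPCR relative quantities become
directly comparable. Both platforms are normalized the same way; projecting
ratio-scaled qPCR data onto a raw-TPM PCA would mix scales. The ratios are
analyzed in $\log_2$ by default (`log2 = TRUE`): multiplicative assay noise
becomes additive and homoscedastic, and the PCA plane is no longer
dominated by the largest spring/winter ratios. Plain ratios remain
available (`log2 = FALSE`).

Samples are then projected onto the top two principal components
(mean-centering, no scaling; deterministic sign convention: the largest
loading entry of each component is positive), and a multinomial logistic
regression of stage on the two coordinates is fitted by minimizing the
L2-penalized softmax negative log-likelihood with a damped Newton solver
(gradient-norm tolerance $10^{-8}$). Two numerical choices differ from
common library defaults and are deliberate:

* the ridge penalty applies to **all** coefficients including intercepts,
  which keeps the full $C$-class parameterization strictly convex (no
  reference class, nonsingular Hessian, unique optimum);
* the penalty is chosen from ten log-spaced values in $[10^{-4}, 10^{4}]$
  by stratified 5-fold cross-validated accuracy, with ties resolved toward
  the **stronger** penalty. Folds are assigned round-robin within class, so
  the fit is a deterministic function of its inputs.

Performance is assessed over repeated stratified train/test splits (500 by
default; the bundled tests and the acceptance script use 50, which is
desk-scale and leaves the mean's precision ample), scoring the
class-support-weighted F1. Prediction ties resolve to the earlier stage in
developmental order. For qPCR samples, `crossplatform_predict()` runs
October normalization → projection with the RNA-seq-fitted PCA →
classification, and reports a chronology-consistency fraction: the share of
chronologically consecutive sample pairs whose predicted stage does not go
backwards.

## Phenology and RT-qPCR quantification

Dormancy release is estimated from the forcing-test series as the first
observation date with $\ge 50\%$ bud burst ("above 50%" is implemented
inclusively at observation resolution, with a `strict` switch), optionally
linearly interpolating the crossing between the bracketing observations —
on a smooth sigmoid sampled fortnightly the interpolated date is within a
day of the true crossing. Stage labels follow a per-cultivar calendar:
organogenesis July–August, paradormancy September, endodormancy from
1 October — conventional, somewhat arbitrary delimitations kept as
configuration, not constants — with dormancy release modeled as a ±7-day
window around the estimated date (samples labeled "release" in practice
are single dates; the window width is configurable).

RT-qPCR quantities come from the relative standard-curve method: ordinary
least squares of Cq on $\log_{10}(\text{quantity})$ over a dilution series
(a valid assay has negative slope; efficiency $= 10^{-1/\text{slope}} - 1$),
inverted as quantity $= 10^{(\mathrm{Cq} - \text{intercept})/\text{slope}}$.
Technical replicate Cq values are averaged before quantification;
biological replicates are kept separate. Each target is normalized by the
arithmetic mean of the reference genes per sample ("average" read
literally; the geometric mean is available), which cancels per-sample
loading differences exactly.

# The synthetic study

All tests run on synthetic data with full ground truth, generated by
`simulate_dataset()`. Its defaults describe one fixed study:

* **Design.** Three cultivars with contrasting dormancy release dates
  (9 Dec 2015, 29 Jan 2016, 26 Feb 2016), sampled at up to 11 dates from
  mid-July to 1 April on 3 replicate trees; sampling stops at each
  cultivar's flowering date, so the early cultivar has 10 dates
  (96 samples in total). A fourth, very late cultivar is measured by
  simulated RT-qPCR only.
* **Profiles.** 2000 genes in 10 clusters (sizes proportional to
  1549 : 70 : 113 : 884 : 156 : 989 : 648 : 612 : 924 : 739). Each cluster
  has a Gaussian-bump latent profile (σ = 30 d) peaking inside its stage,
  from mid-July to early March; the last cluster rises and then
  **plateaus**, because growth-resumption genes stay induced through
  flowering — with a pure bump, late ecodormancy would become
  transcriptionally indistinguishable from summer.
* **Cultivar shifts: a dormancy clock.** Before endodormancy onset all
  cultivars share one clock. Through endodormancy each cultivar's
  effective time runs proportionally faster or slower so that its own
  release date lands on the reference release date; after release, time
  advances in days-since-release. Consequently profiles are nearly
  identical across cultivars until late autumn and diverge afterwards in
  proportion to their chilling requirement, and same-stage samples occupy
  the same region of expression space — the property the classifier
  depends on.
* **Noise.** $\log_2$ amplitude 3 (8-fold swings), per-gene profile noise
  sd 0.1 z-units, negative-binomial counts with dispersion 0.01 around
  TPM-scaled means and library sizes of 0.8–1.2 M (dispersion 0 switches
  to exact expected counts, giving a fully deterministic "clean" regime).
  One planted marker per cluster gets reduced profile noise (factor 0.25)
  and a high baseline — the "clean assayable marker" a study would hope
  exists. qPCR data carry 20% multiplicative noise and Cq noise sd 0.2 on
  technical triplicates; bud-break observations are binomial over 30 buds.
* **Annotations.** Uniform 10% background membership; one planted set per
  cluster and annotation kind at 5× the background rate inside its
  cluster.

What the generator does **not** emulate — and what passing tests therefore
do not show — includes: genes with multiple seasonal peaks or no temporal
structure at all, library-composition artifacts beyond TPM's intrinsic
compositionality, batch effects between years or sequencing runs,
annotation bias toward well-studied genes, and any sequence-level reality
(no reads, isoforms or promoters are simulated). One consequence of TPM
compositionality is visible even in the clean regime: TPM October-ratios
carry a per-sample factor (the denominator moves over the season) that
pure qPCR ratios lack, which can displace a boundary sample by one
adjacent stage in cross-platform prediction.

# Degenerate inputs and edge policies

Zero-variance genes must be filtered before computing Pearson distances
(the error names the gene). Constant rows cannot be z-scored. A cluster
with no eligible marker raises an error naming the binding constraint; the
pipeline additionally drops panel clusters with fewer than 5 genes, the
same logic by which tiny clusters are excluded from panels in practice.
Samples on a line in marker space give a valid rank-1 PCA (second
component spans the null space, zero explained variance); only fully
constant data are rejected. A bud-break series that never reaches the
threshold returns an explicit "not released" result rather than a date.
Missing expression values are rejected, never imputed.

# Known limitations

The DE stand-in's power asymmetry (above) means DEG-restricted clustering
can lose summer- and spring-peaked clusters; the filtered-set default
avoids this for the synthetic study but is a departure from restricting
analysis to DEGs. Hypergeometric p-values are discrete: calibration checks
against the uniform must use randomized p-values, and very small clusters
yield coarse p-value grids. With ten forced clusters, two planted clusters
whose peaks sit ~19 days apart occasionally merge under noise (the
adjusted Rand index stays above 0.95; marker recovery drops to 5/7 in
those draws). Finally, the classifier is a 2-D linear model by design —
stages whose boundary is genuinely nonlinear in the PCA plane (the
organogenesis/paradormancy boundary is the closest call) are predicted
with less margin than the winter stages.
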
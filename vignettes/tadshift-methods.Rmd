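---
title: "Methods: compartments, TADs and coordinated expression after H1 depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartments, TADs and coordinated expression after H1 depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tadshift` implements the integrative analysis used to characterize genome
reorganization after combined knock-down (KD) of linker histone variants
H1.2 and H1.4: paired-condition Hi-C processing, A/B compartment calling and
an eight-category compartment-shift classifier, BIC-penalized TAD
segmentation with border-strength scoring, the per-bin D-score of local
differential interactions, H1-variant ChIP track aggregation and
clustering, and a chromosome-constrained permutation test for coordinated
expression changes within TADs. A synthetic-data generator with planted
ground truth exercises every step end to end; all quantitative claims made
by the package's tests and acceptance script are computed on that
generator, not on the original sequencing data.

# The synthetic study generator

`genome_plan()` materializes a complete two-condition study. Contact counts
for bins $i,j$ at separation $d$ bins (diagonal treated as $d=1$) are
independent Poisson draws with intensity

$$\lambda_{ij} = \text{depth} \cdot d^{-\alpha}\, c_{ij}\, t_{ij}\, g_{ij},$$

where $c_{ij} = 1 \pm \varepsilon$ for same/different planted compartment,
$t_{ij} = 1 + \tau$ within a planted TAD (multiplied by $1+\delta$ in KD),
and $g_{ij} = 1 + \gamma$ in KD beyond the long-range threshold $s^*$.
Optional localized gain regions multiply KD intensities when both bins fall
inside a region, which is how the coupling between the D-score and the
H1.2 landscape is planted (gain placed in low-GC bands).

Defaults define the study conditions: two 20-Mb chromosomes at 100-kb bins
(400 bins, so the full pipeline runs in seconds), $\alpha = 1$ (the
canonical contact-decay exponent at sub-chromosomal scales),
$\varepsilon = 0.3$, 1-Mb alternating compartment blocks, 1-Mb TADs with
$\tau = 1$, $\delta = \gamma = 0.3$, $s^* = 30$ Mb, depth 100 expected
counts at distance 1. Ten percent of bins flip compartment in KD, applied
at whole-block granularity because compartment shifts are regional events.
Distances are measured in bins so tests are resolution-invariant; the
diagonal is simulated but masked from every downstream statistic.

Signal tracks derive from a banded GC model (2-Mb Giemsa-like bands with
stain-dependent GC means, unstained bands spread over 0.38-0.52 GC for the
quartile split). H1.2, H1.5 and H1.0 couple negatively to the GC z-score
(couplings -1.0, -0.8, -0.6), H1.4 and H1X positively (+0.7, +1.0),
H3K9me3 negatively, ATAC positively; Gaussian noise SD 0.5 on a unit
coupling scale. A bins sit 0.04 GC above B bins so that the compartment
eigenvector can be oriented by GC, mirroring how activity tracks orient
compartment calls in practice. Variant tracks share the input track's
baseline, so input subtraction recovers the planted GC-coupled signal.

Genes are placed without overlap inside each planted TAD (Poisson mean 5
per TAD; lengths 5-30 kb) by an exact spacings sampler: gene order is
shuffled and gaps are drawn uniformly over the free space, which samples
the uniform distribution over non-overlapping configurations directly and
fails only when the genes cannot fit at all. Null log2 fold-changes are
N(0, 0.5); coordinated TADs (by default 2 up and 2 down, 8 genes each,
effect size 1 on the log2 scale) shift the mean. Adjusted p-values are
Uniform(0,1) under the null and Beta(0.05, 1) for coordinated genes -
read-level differential-expression calling is out of scope, so p-values
are generated at the distributional level only. Fold-changes are stored
linear; log2 is applied at analysis time.

What the generator does *not* emulate: restriction-fragment structure,
read-level noise and mapping artifacts, replicate structure,
translocations or copy-number variation, nested/hierarchical domains, and
fine-scale loop anchors. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not performance on
real libraries.

# Hi-C processing

Cross-condition comparisons require equal depth: `normalize_depth()`
rescales every chromosome to a common off-diagonal sum (default $10^6$)
with a single multiplicative factor, preserving all ratios. Per-bin biases
are then removed by iterative proportional fitting (`balance()`): rows are
repeatedly divided by their relative sums until the coefficient of
variation of unmasked row sums falls below $10^{-5}$ (default cap 200
iterations; non-convergence is a warning, not an error). Rows with zero
off-diagonal coverage are masked as `NA` and excluded. Total off-diagonal
mass is preserved so depth equalization survives balancing. A dedicated
covariate-based bias model is intentionally not part of the package: the
downstream statistics only require bias-evened matrices, which iterative
balancing provides.

The decay curve (`expected_by_distance()`) pools all cis pairs at each
separation across chromosomes; observed/expected division
(`observed_over_expected()`) masks the diagonal and any distance with zero
expected value, and is idempotent to numerical precision.
`decay_contrast()` summarizes log2(KD/WT) below and above 30 Mb — the
scale that separates the short/medium-range regime from long-range
contacts. The toy genome's 20-Mb chromosomes cannot probe the long-range
regime, so decay-contrast analyses use a 60-Mb chromosome at 500-kb bins.

# Compartments

Per chromosome, `call_compartments()` computes the Pearson correlation
matrix of O/E contact profiles, runs PCA, and considers the first two
components. Rather than visual inspection, the component with the largest
absolute correlation with the GC track is selected and oriented so that
the correlation is positive; A is assigned to positive oriented values.
GC serves as the activity proxy because the H1-variant landscape itself is
organized by GC. Chromosomes whose best GC correlation is below 0.2 are
flagged low-confidence; chromosomes with fewer than ten usable bins are
masked.

`classify_shift()` compares oriented calls: label changes are A-to-B or
B-to-A; same-label bins are sub-classified by the PC1 change against a
threshold defaulting to 20% of the chromosome-wise WT PC1 standard
deviation (no numeric threshold exists in the literature for
compaction/decompaction; a fraction of the component's own scale adapts
across chromosomes and resolutions, and the threshold is configurable).
Shifts are classified on raw PC1 differences, not residuals from any
trend fit. Genes are attached to bins by strand-aware TSS, and per-bin
expression is the mean log2 fold-change of TSS-resident genes.

# TAD segmentation

`segment_tads()` works on O/E values. The objective models within-segment
pairs as Gaussian around a segment-specific mean with a shared variance,
against a chromosome-wide background mean for pairs spanning segments;
because the background term is common, the objective reduces to the
additive gain

$$\text{gain}(a,b) = n_{ab}\,\frac{(\bar{x}_{ab} - \mu_0)^2}{2\sigma_0^2}$$

per segment, minus a BIC penalty of $\tfrac12\log(n_\text{pairs})$ per
border, and dynamic programming maximizes it exactly (verified against
exhaustive search over all partitions on small chromosomes). Only pairs
within 5 Mb of the diagonal enter the likelihood: domain structure lives
at sub-megabase to few-megabase separations, and long-range pairs
contribute only variance. Segments are at least 3 bins; the segmentation
is a full partition of each chromosome (no gap state), and consequently
the published real-data conservation percentages are not expected from
this package. Gains are computed in O(1) per segment from two-dimensional
prefix sums, so a 400-bin chromosome segments in well under a second.

## Border strength

Strength quantifies how robust each border of the optimal path is to a
degradation of its score, on the canonical 1-10 integer scale. The border
path is degraded in ten steps of one fixed offset unit; at step $r$ a
border survives while its marginal contribution — the objective loss from
removing it and merging its flanking segments — still matches the
accumulated reduction $r\cdot\text{offset}$. Strength is the number of
surviving steps, floored at 1. The offset unit is sized per chromosome so
the ten-step ladder spans the path's marginal-gain range (the strongest
border scores 10). Early designs that re-ran the full DP with penalties
painted onto the previous path were abandoned: the programme simply
sidesteps such penalties by nudging borders one or two bins, or merges
long runs wholesale once the per-border penalty reaches the per-segment
gain scale, collapsing all strengths — the marginal-contribution ladder is
the formulation that actually yields the described behaviour. Because the
scale is per-chromosome-relative, cross-condition comparisons must share
one scale: compute strengths on one condition and pass its
`$strength_offset` to the other, as `run_pipeline()` does.

Borders are matched across conditions greedily by nearest position within
100 kb (ties to the leftward partner, each border used once): exact
matches are conserved, within-tolerance matches shifted, the rest
non-conserved, with unmatched KD borders reported de novo. Strength
dynamics per category use Mann-Whitney tests; non-conserved WT borders are
compared against the pooled de novo KD borders.

# D-score

For each 100-kb bin, the D-score is the mean of the KD-WT contact
difference with all bins within ±2 Mb (boundary inclusive, diagonal
excluded, chromosome edges use available neighbors). It is computed on
depth-equalized matrices — the differential map is a difference of
comparable contact values, not of O/E ratios — and an O/E-based variant is
available by passing O/E matrices through the same interface. Signed
means are used: a bin surrounded by gained interactions is positive.
Exactness is guarded by a brute-force oracle; swapping conditions negates
the score identically, and scaling the difference scales the score
linearly (it is not invariant to adding a constant to both matrices, which
is intentional and documented).

# Tracks, bands and groups

Aggregation over intervals is bp-weighted (a partial overlap contributes
its fraction of the bin) via interval-tree overlap. Unstained (gneg) G
bands are split into four equal-size groups by GC, Gneg1 highest to Gneg4
lowest, with boundary ties going to the higher-GC group. The "H1.2/H1X
ratio" that groups TADs is implemented as the difference of per-TAD mean
input-subtracted signals, because input subtraction produces negative
values that break a literal quotient; a log2-ratio mode exists for
strictly positive tracks. Variant profiles are z-scored per variant
(zero-variance profiles are left unscaled with a warning) and clustered
with Euclidean distance and complete linkage; the 2-group cut recovers the
planted {H1.2, H1.5, H1.0} versus {H1.4, H1X} split.

# Coordinated expression within TADs

Genes are classified up/down at linear FC 1.4 and adjusted p 0.05 (the
canonical thresholds for this system), assigned to TADs by TSS
(whole-gene-majority assignment is available), and TADs are classed Up,
Dw, UpDw or Control by the presence of deregulated genes in each
direction. The coordination histogram bins each eligible TAD (at least 4
genes) by its proportion of genes with FC > 1 into ten equal bins, 1.0
included in the top bin.

The null reference randomizes gene positions per chromosome, preserving
lengths and forbidding overlap, using the same exact spacings sampler as
the generator (uniform over valid configurations by construction, so no
retry loop or failure mode exists unless genes cannot fit at all). The
expected histogram is the mean over permutations (mean, not median, so
expected counts are additive and the chi-square is well defined);
observed counts are compared to expected counts with a Pearson chi-square
over bins pooled so that every group has expected count at least 1, with
degrees of freedom one less than the number of groups. Calibration under
the uncoordinated null sits near the nominal level (rejection rate about
2-6% at $\alpha = 0.05$ across replicate datasets), and planted
coordination (eight TADs with at least 90% up-regulated genes) inflates
the top-bin observed/expected ratio several-fold with p well below 0.05
at 1,000 permutations. The default 10,000 permutations are used in the
full pipeline; tests and the acceptance script use 500-2,000, which is
ample for these effect sizes.

Whether coordination is assessed on WT or condition-merged TADs is a free
choice; WT segmentations are used throughout.

# Pipeline and determinism

`run_pipeline()` chains every stage, writes only plain-text outputs
(COO/TSV/bedGraph/BED/JSON) and a manifest with md5 checksums, parameters
and per-stage summaries. All randomness flows from the plan seed plus
fixed per-purpose offsets, and every sampler runs in a private RNG stream
that restores the caller's state, so reruns are byte-identical and
library-side RNG use cannot perturb results. Per-stage outputs are
re-readable with the package's readers, making each stage re-runnable
from its persisted inputs.

# Known limitations

* The segmentation objective is a behavioral, not bit-level, reconstruction
  of dynamic-programming TAD callers; real-data border statistics will
  differ from published values obtained with other implementations.
* Border strengths are relative within a chromosome; comparing absolute
  strengths across chromosomes or conditions requires a shared offset
  scale.
* Trans-chromosomal contacts, nested domains, and sub-compartment types
  are out of scope.
* The permutation test treats TADs as fixed while genes move; it does not
  model uncertainty in the segmentation itself.
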
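# tadshift

Integrative Hi-C + ChIP-seq + RNA-seq analysis of chromatin reorganization
after linker-histone (H1) depletion, built as a tested R package plus a
numbered analysis workflow. It is aimed at computational epigenomics work
on paired-condition Hi-C experiments (wild-type versus knock-down) where
the questions are: which genomic bins change A/B compartment, how TAD
borders and their strengths respond, where local interactions are gained
or lost, and whether resident genes change expression in a coordinated
way within TADs.

Everything runs end to end on a synthetic-data generator with planted
ground truth (compartments, TAD borders with insulation depths, GC-coupled
H1-variant tracks, coordinated TADs), so every claim the tests make is
checked against a known answer.

## Methods at a glance

* **Contact matrices** — dense-TSV/COO text I/O, per-chromosome depth
  equalization, ICE-style iterative balancing (masking zero-coverage rows),
  observed/expected (O/E) transformation, distance-decay curves and the
  log2(KD/WT) contrast below/above 30 Mb.
* **Compartments** — per-chromosome PCA of the O/E correlation matrix; the
  component (PC1 or PC2) best correlated with GC is chosen and oriented so
  A = positive. Shifts between conditions fall into eight categories:
  `A-to-B`, `B-to-A`, stable `AA`/`BB`, and compaction/decompaction
  sub-categories (`AA+A`, `AA-A`, `BB+B`, `BB-B`) by the PC1 change against
  a threshold of 0.2 x sd(PC1).
* **TADs** — exact dynamic-programming segmentation maximizing a
  segment-mean Gaussian likelihood gain `n (x̄ − μ₀)² / 2σ₀²` per segment
  with a BIC penalty of ½·log(n_pairs) per border; border strength 1–10 by
  the number of score-degradation steps a border's marginal contribution
  survives; density score = within-TAD / between-TAD contact mass; greedy
  border matching (conserved / shifted ≤ 100 kb / non-conserved, de novo).
* **D-score** — per 100-kb bin, the mean KD−WT contact difference within a
  ±2 Mb window; positive = locally gained interactions after knock-down;
  correlated (Spearman) with H1.2 and H1X tracks.
* **Tracks** — RPM input subtraction, bp-weighted aggregation over
  arbitrary intervals, Giemsa-band classification (Gneg1–4 by GC quartile),
  TAD groups by H1.2/H1X balance, Euclidean/complete-linkage clustering of
  variant profiles.
* **Coordinated expression** — DE at FC ≥ 1.4 and adjusted p ≤ 0.05, TAD
  classes Control/Up/Dw/UpDw, the per-TAD proportion-up histogram
  (TADs with ≥ 4 genes), and a permutation null that redistributes genes
  uniformly without overlap within their own chromosomes (10,000 draws by
  default) compared by Pearson chi-square.

## Worked example

```r
library(tadshift)

plan <- genome_plan(seed = 1)                  # default toy study
wt <- balance(normalize_depth(simulate_hic(plan, "WT")))
kd <- balance(normalize_depth(simulate_hic(plan, "KD")))
tracks <- simulate_tracks(plan)

calls <- lapply(list(wt, kd), \(m)
  call_compartments(observed_over_expected(m), tracks$GC))
cls <- classify_shift(calls[[1]], calls[[2]])
mean(calls[[1]]$bins$label == plan_truth(plan)$bins$comp_wt)
#> [1] 1                               # 100% of planted labels recovered
mean(cls$bins$category %in% c("A-to-B", "B-to-A"))
#> [1] 0.1                             # the planted 10% flip fraction

seg <- border_strength(wt, segment_tads(wt))
seg
#> tad_segmentation [WT]: 40 TADs, 38 borders, density 1.848
```

The numbers mean: every 100-kb bin received the planted compartment label,
exactly the planted 10% of bins are called as compartment shifts, and the
caller tiles the two toy chromosomes into the planted ~1-Mb TADs with an
within/between contact-mass ratio of 1.85.

## Analysis workflow

The numbered drivers under `analysis/` run the study as a narrative, each
writing its tables under `results/` (run them in order; stage 1 writes the
simulated inputs the later stages read):

```sh
Rscript analysis/01_simulate.R          # simulate the paired-condition study
Rscript analysis/02_normalize_decay.R   # balancing + decay contrast
Rscript analysis/03_compartments.R      # A/B calls and the 8-category shifts
Rscript analysis/04_tads.R              # TADs, border strength dynamics
Rscript analysis/05_dscore_tracks.R     # D-score, G bands, variant clusters
Rscript analysis/06_tad_expression.R    # TAD classes + permutation test
```

Representative output (printed by the scripts): decay contrast −0.18
below / +0.31 above 30 Mb under planted long-range gain; Spearman(D, H1.2)
= 0.47 and Spearman(D, H1X) = −0.46 under the coupled plan; variant
2-group cut {H1.2, H1.5, H1.0} vs {H1.4, H1X}; coordination chi-square
38.3 (p ≈ 3e-06) with a top-bin observed/expected ratio of 4.2 against
10,000 gene-position randomizations.

Equivalently, `run_pipeline(pipeline_config(plan = genome_plan(seed = 1)))`
runs all stages in one call and writes a manifest with md5 checksums;
reruns with the same seed are byte-identical.

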
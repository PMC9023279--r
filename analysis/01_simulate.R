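#!/usr/bin/env Rscript
# Stage 1 - simulate the two-condition study (WT vs H1 KD) on the default
# toy genome: 2 chromosomes x 20 Mb at 100-kb bins, checkerboard A/B
# compartments (contrast 0.3), 1-Mb TADs (insulation 1.0), 10% of bins
# flipped in KD, intra-TAD gain 0.3, long-range gain 0.3, GC-coupled H1
# tracks and genes coordinated in 2 up / 2 down TADs.
library(tadshift)

plan <- genome_plan(seed = 1)
sim <- simulate_study(plan)

dir.create("results/01_simulation", recursive = TRUE, showWarnings = FALSE)
write_contact_matrix(sim$wt, "results/01_simulation", "WT", "coo")
write_contact_matrix(sim$kd, "results/01_simulation", "KD", "coo")
for (nm in names(sim$tracks))
  write_bedgraph(sim$tracks[[nm]],
                 file.path("results/01_simulation",
                           paste0("track_", gsub("[^A-Za-z0-9_]", "_", nm),
                                  ".bedGraph")))
write_genes(sim$genes, "results/01_simulation/genes.bed")
jsonlite::write_json(list(bins = sim$truth$bins, borders = sim$truth$borders,
                          coord_tads = sim$truth$coord_tads),
                     "results/01_simulation/truth.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("simulated %d bins, %d genes; WT total counts %.0f, KD %.0f",
                sum(plan$binning$n_bins), nrow(sim$genes),
                sum(sapply(sim$wt$mats, sum)), sum(sapply(sim$kd$mats, sum))))
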
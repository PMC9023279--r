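test_that("DE classification reproduces hand-computed labels", {
  st <- classify_de(toy_genes())
  expect_equal(st, c("up", "up", "unchanged", "unchanged", "down", "down",
                     "unchanged", "unchanged", "unchanged", "up", "unchanged",
                     "unchanged"))
  expect_error(classify_de(transform(toy_genes(), fc = c(-1, rep(1, 11)))),
               "positive")
  expect_error(classify_de(toy_genes(), fc_thresh = 0), "positive")
})

test_that("DE classification is monotone in the fold-change", {
  g <- toy_genes()
  rank_of <- c(down = 1, unchanged = 2, up = 3)
  base <- rank_of[classify_de(g)]
  g2 <- g; g2$fc <- g$fc * 1.5
  expect_true(all(rank_of[classify_de(g2)] >= base))
})

test_that("genes are assigned to the TAD holding their TSS", {
  plan <- genome_plan(chrom_lengths = c(chrA = 4e6), bin_size = 1e5,
                      tad_bp = 1e6, n_coord_up = 0, n_coord_down = 0, seed = 1)
  seg <- plan_segmentation(plan)
  genes <- data.frame(
    gene_id = c("a", "b", "c"), chrom = "chrA",
    start = c(1e6, 0.95e6, 3.5e6), end = c(1.2e6, 1.4e6, 3.9e6),
    strand = c("+", "+", "-"), baseline = 1, fc = 1, padj = 1)
  m <- assign_genes_to_tads(genes, seg)
  expect_equal(m$tad, c("chrA:2",   # TSS exactly at a boundary: downstream TAD
                        "chrA:1",   # spans two TADs, TSS in the first
                        "chrA:4"))  # minus strand: TSS = end - 1
  # round trip: each TSS lies inside its TAD interval
  tss <- c(1e6, 0.95e6, 3.9e6 - 1)
  idx <- as.integer(sub(".*:", "", m$tad))
  expect_true(all(tss >= seg$tads$start_bp[idx] & tss < seg$tads$end_bp[idx]))
  bad <- transform(genes, end = 5e6)
  expect_error(assign_genes_to_tads(bad, seg), "beyond chromosome end")
})

test_that("TAD response classes follow the Up/Dw/UpDw/Control rules", {
  mapping <- data.frame(tad = c("chrA:1", "chrA:1",
                                "chrA:2", "chrA:2",
                                "chrA:3", "chrA:3", "chrA:4"),
                        fc = c(2, 1.1, 0.5, 2, 0.4, 0.6, 1))
  st <- c("up", "unchanged", "down", "up", "down", "down", "unchanged")
  res <- classify_tads(mapping, st)
  expect_equal(res$class[match(paste0("chrA:", 1:4), res$tad)],
               c("Up", "UpDw", "Dw", "Control"))
  expect_true(all(res$n_up + res$n_down <= res$n_genes))
  # with a segmentation, gene-less TADs appear as flagged Controls
  plan <- genome_plan(chrom_lengths = c(chrA = 5e6), bin_size = 1e5,
                      tad_bp = 1e6, n_coord_up = 0, n_coord_down = 0, seed = 1)
  res2 <- classify_tads(mapping, st, plan_segmentation(plan))
  empty <- res2[res2$tad == "chrA:5", ]
  expect_equal(empty$class, "Control")
  expect_equal(empty$n_genes, 0L)
  expect_true(empty$empty)
})

test_that("the coordination histogram counts proportions into decile bins", {
  mapping <- data.frame(
    tad = c(rep("chrA:1", 4), rep("chrA:2", 5), rep("chrA:3", 3)),
    fc = c(1.2, 1.5, 0.8, 2.0,            # 3/4 up -> bin 0.7-0.8
           2, 2, 2, 2, 2,                 # all up -> top bin
           0.5, 0.5, 0.5))                # only 3 genes: excluded
  h <- coordination_histogram(mapping)
  expect_equal(h$n_eligible, 2)
  expect_equal(unname(h$counts[8]), 1)
  expect_equal(unname(h$counts[10]), 1)
  expect_equal(sum(h$counts), h$n_eligible)
  # brute-force recount oracle on the same toy
  per <- tapply(mapping$fc > 1, mapping$tad, mean)[
    tapply(mapping$fc, mapping$tad, length) >= 4]
  expect_equal(sort(h$per_tad$prop_fc_up), sort(as.numeric(per)))
  expect_error(coordination_histogram(mapping, min_genes = 6), "no TADs")
})

test_that("uniform non-overlapping placement preserves lengths and bounds", {
  set.seed(42)
  lens <- sample(100:500, 30, replace = TRUE)
  for (i in 1:50) {
    st <- tadshift:::place_nonoverlap(lens, 2e4)
    o <- order(st)
    expect_true(all(st[o][-1] >= (st + lens)[o][-length(lens)]))
    expect_true(all(st >= 0 & st + lens <= 2e4))
  }
  expect_error(tadshift:::place_nonoverlap(c(600, 600), 1000), "overlap")
})

test_that("the permutation null is reproducible under a fixed seed", {
  plan <- null_gene_plan(3)
  genes <- simulate_genes(plan)
  seg <- plan_segmentation(plan)
  r1 <- permutation_null(genes, seg, n_perm = 1, seed = 99)
  r2 <- permutation_null(genes, seg, n_perm = 1, seed = 99)
  expect_identical(r1$expected, r2$expected)
})

test_that("planted >=90%-up TADs inflate the top histogram bin", {
  plan <- coord_plan(13)
  genes <- simulate_genes(plan)
  wt <- cached("coord_wt_13", balance(normalize_depth(simulate_hic(plan, "WT"))))
  seg <- segment_tads(wt)
  res <- cached("coord_res_13",
                permutation_null(genes, seg, n_perm = 1000, seed = 13))
  expect_gt(res$ratio[10], 1)
  expect_lt(res$p, 0.05)
  expect_gte(res$df, 1)
})

test_that("group summaries separate planted covariate differences", {
  set.seed(5)
  groups <- rep(c("coord", "other"), c(10, 30))
  covs <- data.frame(h1_2 = c(rnorm(10, 2), rnorm(30, 0)),
                     flat = rnorm(40))
  gs <- summarize_tad_groups(groups, covs)
  s <- gs$summary
  expect_lt(s$mw_p[s$covariate == "h1_2" & s$group == "coord"], 0.05)
  expect_gt(gs$kruskal[gs$kruskal$covariate == "flat", "kruskal_p"], 0.05)
  expect_lt(gs$kruskal[gs$kruskal$covariate == "h1_2", "kruskal_p"], 0.05)
})

test_that("coordination planted in low-GC TADs shows elevated H1.2", {
  plan <- genome_plan(seed = 13, n_coord_up = 8, n_coord_down = 0,
                      coord_effect = 1.5, coord_low_gc = TRUE)
  seg <- plan_segmentation(plan)
  tr <- simulate_tracks(plan)
  ids <- paste0(seg$tads$chrom, ":",
                unlist(lapply(rle(seg$tads$chrom)$lengths, seq_len)))
  coord_ids <- with(plan$coord_tads, paste0(chrom, ":", tad_index))
  groups <- ifelse(ids %in% coord_ids, "coordinated", "background")
  ivs <- data.frame(chrom = seg$tads$chrom, start = seg$tads$start_bp,
                    end = seg$tads$end_bp)
  h1_2 <- aggregate_track(input_subtract(tr$H1.2, tr$input), ivs)$mean
  gs <- summarize_tad_groups(groups, data.frame(h1_2 = h1_2))
  s <- gs$summary
  expect_lt(s$mw_p[s$group == "coordinated"], 0.05)
  expect_gt(s$median[s$group == "coordinated"],
            s$median[s$group == "background"])
})

test_that("the class-by-category cross-tab has consistent margins", {
  plan <- default_plan(2)
  genes <- simulate_genes(plan)
  seg <- plan_segmentation(plan)
  mapping <- assign_genes_to_tads(genes, seg)
  tsum <- classify_tads(mapping, classify_de(genes), seg)
  truth <- plan_truth(plan)
  cls <- classify_shift(
    compartment_call_from_labels(plan$binning, truth$bins$comp_wt),
    compartment_call_from_labels(plan$binning, truth$bins$comp_kd,
                                 condition = "KD"))
  xt <- tad_compartment_crosstab(tsum, seg, cls)
  expect_equal(sum(xt$table), nrow(tsum))
  expect_equal(unname(rowSums(xt$table)),
               unname(as.vector(table(tsum$class)[rownames(xt$table)])))
})
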
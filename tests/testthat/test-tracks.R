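test_that("input subtraction is elementwise and unit-tagged", {
  b <- genome_binning(c(chrA = 2e5), 1e5)
  chip <- binned_track(b, c(2, 3), units = "RPM")
  input <- binned_track(b, c(1, 1), units = "RPM")
  out <- input_subtract(chip, input)
  expect_equal(out$value, c(1, 2))
  expect_equal(attr(out, "units"), "input-subtracted")
  expect_true(all(input_subtract(chip, chip)$value == 0))
  other <- binned_track(genome_binning(c(chrA = 3e5), 1e5), c(1, 1, 1))
  expect_error(input_subtract(chip, other), "different intervals")
})

test_that("aggregation equals a per-bp brute-force average", {
  # toy 100-bp genome in 10-bp bins
  b <- genome_binning(c(chrA = 100), 10)
  set.seed(1)
  vals <- rnorm(10)
  tr <- binned_track(b, vals)
  per_bp <- rep(vals, each = 10)
  ivs <- data.frame(chrom = "chrA", start = c(0, 7, 35, 90),
                    end = c(20, 33, 80, 100))
  agg <- aggregate_track(tr, ivs)
  for (r in seq_len(nrow(ivs)))
    expect_equal(agg$mean[r], mean(per_bp[(ivs$start[r] + 1):ivs$end[r]]))
  # constant track -> constant means; no overlap -> NA
  cst <- binned_track(b, rep(4, 10))
  expect_true(all(aggregate_track(cst, ivs)$mean == 4))
  off <- data.frame(chrom = "chrB", start = 0, end = 10)
  expect_true(is.na(aggregate_track(tr, off)$mean))
})

test_that("aggregation after subtraction equals subtraction of aggregates", {
  b <- genome_binning(c(chrA = 50e5), 1e5)
  set.seed(1)
  chip <- binned_track(b, rnorm(50, 5), units = "RPM")
  input <- binned_track(b, rnorm(50, 1), units = "RPM")
  ivs <- data.frame(chrom = "chrA", start = c(0, 12e5), end = c(12e5, 50e5))
  lhs <- aggregate_track(input_subtract(chip, input), ivs)$mean
  rhs <- aggregate_track(chip, ivs)$mean - aggregate_track(input, ivs)$mean
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("G bands split gneg bands by GC quartile with stable ties", {
  b <- genome_binning(c(chrA = 16e5), 1e5)
  gcv <- c(0.30, 0.34, 0.38, 0.42, 0.46, 0.50, 0.54, 0.58,
           rep(0.45, 8))
  gc <- binned_track(b, gcv, units = "GC-fraction")
  bands <- data.frame(chrom = "chrA", start = seq(0, 15e5, 1e5),
                      end = seq(1e5, 16e5, 1e5),
                      stain = c(rep("gneg", 8), "gpos25", "gpos50", "gpos75",
                                "gpos100", rep("gneg", 4)))
  out <- classify_gbands(bands, gc)
  # gneg bands 1..8 have GC 0.30..0.58: top two are Gneg1, bottom two Gneg4
  expect_equal(out$class[7:8], c("Gneg1", "Gneg1"))
  expect_equal(out$class[1:2], c("Gneg4", "Gneg4"))
  expect_equal(out$class[9:12], c("Gpos25", "Gpos50", "Gpos75", "Gpos100"))
  # the four tied 0.45 bands share one rank: assigned to the lower-index group
  tied <- out$class[13:16]
  expect_equal(length(unique(tied)), 1)
  # group sizes differ by at most 1 when no ties
  out2 <- classify_gbands(bands[1:8, ], gc)
  expect_true(all(table(out2$class) == 2))
  expect_error(classify_gbands(bands[bands$stain != "gneg", ], gc), "gneg")
})

test_that("H1 ratio groups are equal-size and ordered", {
  b <- genome_binning(c(chrA = 8e6), 1e6)
  h1_2 <- binned_track(b, 1:8, units = "input-subtracted")
  h1x <- binned_track(b, rep(0, 8), units = "input-subtracted")
  tads <- data.frame(chrom = "chrA", start = seq(0, 7e6, 1e6),
                     end = seq(1e6, 8e6, 1e6))
  g <- h1_ratio_groups(tads, h1_2, h1x)
  expect_equal(g$group, rep(1:4, each = 2))
  # sizes differ by <= 1 for non-divisible counts
  g2 <- h1_ratio_groups(tads[1:7, ], h1_2, h1x)
  expect_lte(diff(range(table(g2$group))), 1)
  expect_error(h1_ratio_groups(tads[1:3, ], h1_2, h1x, n_groups = 4), "exceeds")
})

test_that("high-ratio TAD groups carry higher planted H1.2", {
  plan <- cached("track_plan_7",
                 genome_plan(seed = 7, chrom_lengths = c(chr1 = 100e6,
                                                         chr2 = 100e6)))
  tr <- cached("tracks_7", simulate_tracks(plan))
  seg <- plan_segmentation(plan)
  tads <- data.frame(chrom = seg$tads$chrom, start = seg$tads$start_bp,
                     end = seg$tads$end_bp)
  h1_2 <- input_subtract(tr$H1.2, tr$input)
  h1x <- input_subtract(tr$H1X, tr$input)
  g <- h1_ratio_groups(tads, h1_2, h1x)
  expect_gt(mean(g$h1_2[g$group == 4]), mean(g$h1_2[g$group == 1]))
})

test_that("variant clustering recovers the two planted GC-coupling groups", {
  plan <- cached("track_plan_7",
                 genome_plan(seed = 7, chrom_lengths = c(chr1 = 100e6,
                                                         chr2 = 100e6)))
  tr <- cached("tracks_7", simulate_tracks(plan))
  variants <- c("H1.2", "H1.5", "H1.0", "H1.4", "H1X")
  bm <- do.call(rbind, lapply(variants, function(v)
    aggregate_track(input_subtract(tr[[v]], tr$input), plan$bands)$mean))
  rownames(bm) <- variants
  cl <- cluster_variant_profiles(bm)
  g <- cl$groups
  expect_equal(g[["H1.2"]], g[["H1.5"]])
  expect_equal(g[["H1.2"]], g[["H1.0"]])
  expect_equal(g[["H1.4"]], g[["H1X"]])
  expect_false(g[["H1.2"]] == g[["H1X"]])
  # permuting the interval order leaves the linkage invariant
  perm <- sample(ncol(bm))
  cl2 <- cluster_variant_profiles(bm[, perm])
  expect_equal(cl2$hclust$height, cl$hclust$height, tolerance = 1e-12)
  expect_equal(cl2$groups, cl$groups)
})

test_that("clustering groups identical rows and guards constant rows", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  cl <- cluster_variant_profiles(m)
  expect_equal(cl$groups[["a"]], cl$groups[["b"]])
  expect_false(cl$groups[["a"]] == cl$groups[["c"]])
  expect_warning(cluster_variant_profiles(rbind(m, d = c(1, 1, 1, 1))),
                 "zero-variance")
})

test_that("peak densities and accessibility changes follow their definitions", {
  ivs <- data.frame(chrom = "chrA", start = 0, end = 1e6)
  peaks <- data.frame(chrom = "chrA", start = seq(0, 9e5, 1e5), end = seq(0, 9e5, 1e5) + 400)
  res <- accessibility_change(peaks, peaks, ivs)
  expect_equal(res$per_interval$wt, 10)     # 10 peaks per Mb
  expect_equal(res$per_interval$diff, 0)
})

test_that("planted KD peak gain concentrates in the low-ratio TAD group", {
  plan <- genome_plan(seed = 10)
  tr <- simulate_tracks(plan)
  seg <- plan_segmentation(plan)
  tads <- data.frame(chrom = seg$tads$chrom, start = seg$tads$start_bp,
                     end = seg$tads$end_bp)
  g <- h1_ratio_groups(tads, input_subtract(tr$H1.2, tr$input),
                       input_subtract(tr$H1X, tr$input))
  res <- accessibility_change(simulate_atac_peaks(plan, "WT"),
                              simulate_atac_peaks(plan, "KD"),
                              tads, groups = g$group)
  gs <- res$group_summary
  expect_gt(gs$median_diff[gs$group == "1"], gs$median_diff[gs$group == "4"])
  expect_lt(res$kruskal_p, 0.05)
})

test_that("bedGraph round-trips a track", {
  b <- genome_binning(c(chrA = 5e5), 1e5)
  tr <- binned_track(b, c(0.1, -2.5, 3, 0, 7))
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(back$value, tr$value, tolerance = 1e-12)
  expect_equal(back$start, tr$start)
})
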
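test_that("two enriched blocks force exactly one border at the junction", {
  M <- matrix(1, 80, 80)
  M[1:40, 1:40] <- 10
  M[41:80, 41:80] <- 10
  diag(M) <- 20
  seg <- segment_tads(toy_cm(M))
  expect_equal(seg$borders$bin, 40)
  expect_equal(nrow(seg$tads), 2)
})

test_that("a uniform matrix yields a single TAD", {
  seg <- segment_tads(toy_cm(matrix(3, 60, 60)))
  expect_equal(nrow(seg$borders), 0)
  expect_equal(nrow(seg$tads), 1)
})

test_that("short chromosomes collapse to one TAD without error", {
  seg <- segment_tads(toy_cm(matrix(2, 10, 10)))
  expect_equal(nrow(seg$tads), 1)
})

test_that("planted borders are recovered within one bin at 50 kb", {
  plan <- tad_recovery_plan(6)
  wt <- cached("tad_wt_6", balance(normalize_depth(simulate_hic(plan, "WT"))))
  seg <- cached("tad_seg_6", segment_tads(wt))
  truth <- plan_truth(plan)
  hit <- vapply(truth$borders$bin,
                function(b) any(abs(seg$borders$bin - b) <= 1), TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("the DP matches exhaustive search on small chromosomes", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(12:25, 1)
    M <- matrix(stats::rexp(n * n), n)
    if (rep %% 2 == 0) {     # half the cases get a planted block
      a <- sample(1:(n - 4), 1); b <- a + sample(3:5, 1)
      M[a:b, a:b] <- M[a:b, a:b] + 3
    }
    M <- (M + t(M)) / 2
    cm <- toy_cm(M, bin_size = 1e5, norm = "oe")
    seg <- segment_tads(cm, max_tads = 4, band_bp = 1e9)
    dp_starts <- seg$tads$start_bin + 1L
    objs <- vapply(all_partitions(n, 3L), function(st)
      oracle_objective(cm$mats[[1]], st), numeric(1))
    expect_equal(oracle_objective(cm$mats[[1]], dp_starts), max(objs),
                 tolerance = 1e-9)
  }
})

test_that("segmentations are full partitions", {
  seg <- cached("tad_seg_6", segment_tads(
    cached("tad_wt_6", balance(normalize_depth(simulate_hic(tad_recovery_plan(6), "WT"))))))
  td <- seg$tads
  expect_equal(td$start_bin[1], 0)
  expect_equal(td$start_bin[-1], td$end_bin[-nrow(td)])
  expect_equal(td$end_bin[nrow(td)], seg$binning$n_bins[1])
})

test_that("border strength is 10 for a sharp isolated border and bounded in 1..10", {
  M <- matrix(1, 80, 80)
  M[1:40, 1:40] <- 10; M[41:80, 41:80] <- 10; diag(M) <- 20
  cm <- toy_cm(M)
  seg <- border_strength(cm, segment_tads(cm))
  expect_equal(seg$borders$strength, 10)
  plan <- tad_ladder_plan(6)
  wt <- cached("ladder_wt_6", balance(normalize_depth(simulate_hic(plan, "WT"))))
  seg2 <- cached("ladder_seg_6", border_strength(wt, segment_tads(wt)))
  expect_true(all(seg2$borders$strength >= 1 & seg2$borders$strength <= 10))
  expect_true(all(seg2$borders$strength == round(seg2$borders$strength)))
})

test_that("strength increases with planted insulation depth", {
  plan <- tad_ladder_plan(6)
  wt <- cached("ladder_wt_6", balance(normalize_depth(simulate_hic(plan, "WT"))))
  seg <- cached("ladder_seg_6", border_strength(wt, segment_tads(wt)))
  m <- merge(plan_truth(plan)$borders, seg$borders, by = c("chrom", "bin"))
  expect_gt(nrow(m), 8)
  expect_gt(stats::cor(m$depth, m$strength, method = "spearman"), 0.8)
})

test_that("a weak boundary scores below a strong one in the same simulation", {
  plan <- genome_plan(chrom_lengths = c(chr1 = 7.5e6), bin_size = 50e3,
                      tad_bp = 2.5e6, tau = c(1.5, 0.1, 1.5),
                      n_coord_up = 0, n_coord_down = 0, seed = 6)
  wt <- balance(normalize_depth(simulate_hic(plan, "WT")))
  seg <- border_strength(wt, segment_tads(wt))
  truth <- plan_truth(plan)
  m <- merge(truth$borders, seg$borders, by = c("chrom", "bin"))
  if (nrow(m) == 2)     # both borders found: weak (depth 0.1) scores lower
    expect_lt(m$strength[which.min(m$depth)], m$strength[which.max(m$depth)])
  else expect_lte(nrow(m), 2)
})

test_that("density score counts within over across mass", {
  plan <- genome_plan(chrom_lengths = c(chrA = 4e5), bin_size = 1e5,
                      tad_bp = 2e5, n_coord_up = 0, n_coord_down = 0, seed = 1)
  seg <- plan_segmentation(plan)
  U <- matrix(1, 4, 4)
  cm <- contact_matrix(list(chrA = U), plan$binning)
  expect_equal(density_score(cm, seg), 2 / 4)
  # zero inter-TAD mass -> undefined sentinel
  B <- matrix(0, 4, 4)
  B[1:2, 1:2] <- 1; B[3:4, 3:4] <- 1
  expect_equal(density_score(contact_matrix(list(chrA = B), plan$binning), seg),
               Inf)
})

test_that("intra-TAD gain raises the KD density score", {
  plan <- tad_recovery_plan(6)
  wt <- cached("tad_wt_6", balance(normalize_depth(simulate_hic(plan, "WT"))))
  kd <- balance(normalize_depth(simulate_hic(plan, "KD")))
  seg <- plan_segmentation(plan)
  expect_gt(density_score(kd, seg), density_score(wt, seg))
})

test_that("border matching applies the greedy tolerance rules", {
  b <- genome_binning(c(chrA = 15e6), 50e3)
  mk <- function(bins, cond) structure(list(
    tads = data.frame(chrom = "chrA", start_bin = c(0, bins),
                      end_bin = c(bins, 300),
                      start_bp = c(0, bins) * 5e4, end_bp = c(bins, 300) * 5e4),
    borders = data.frame(chrom = "chrA", bin = bins, bp = bins * 5e4,
                         strength = 5),
    binning = b, condition = cond), class = "tad_segmentation")
  m <- match_borders(mk(c(100, 200), "WT"), mk(c(100, 201), "KD"),
                     tol_bp = 100e3)
  expect_equal(m$matches$category, c("conserved", "shifted"))
  expect_equal(m$matches$offset, c(0, 1))
  # identical segmentations: all conserved
  m2 <- match_borders(mk(c(50, 150), "WT"), mk(c(50, 150), "KD"))
  expect_true(all(m2$matches$category == "conserved"))
  # unmatched on either side
  m3 <- match_borders(mk(100, "WT"), mk(250, "KD"), tol_bp = 100e3)
  expect_equal(m3$matches$category, "non-conserved")
  expect_equal(m3$de_novo$bin, 250)
  # bookkeeping: categories partition the WT borders
  expect_equal(nrow(m$matches), 2)
})

test_that("intra-TAD gain shifts conserved border strengths upward", {
  plan <- genome_plan(chrom_lengths = c(chr1 = 40e6), bin_size = 50e3,
                      tad_bp = 2e6, tau = 1.0, delta = 0.5, flip_fraction = 0,
                      seed = 6)
  wtn <- balance(normalize_depth(simulate_hic(plan, "WT")))
  kdn <- balance(normalize_depth(simulate_hic(plan, "KD")))
  seg_wt <- border_strength(wtn, segment_tads(wtn))
  seg_kd <- border_strength(kdn, segment_tads(kdn),
                            offset = seg_wt$strength_offset)
  dyn <- border_strength_dynamics(match_borders(seg_wt, seg_kd), seg_wt, seg_kd)
  cons <- dyn[dyn$category == "conserved", ]
  expect_gt(cons$mean_kd, cons$mean_wt)
  expect_lt(cons$p, 0.05)
})

test_that("identical conditions show no strength differences", {
  plan <- tad_recovery_plan(6)
  wt <- cached("tad_wt_6", balance(normalize_depth(simulate_hic(plan, "WT"))))
  seg <- border_strength(wt, cached("tad_seg_6", segment_tads(wt)))
  dyn <- border_strength_dynamics(match_borders(seg, seg), seg, seg)
  cons <- dyn[dyn$category == "conserved", ]
  expect_equal(cons$mean_wt, cons$mean_kd)
  expect_gt(cons$p, 0.9)
})

test_that("intra/inter differential matches direct arithmetic and brute force", {
  plan <- genome_plan(chrom_lengths = c(chrA = 4e5), bin_size = 1e5,
                      tad_bp = 2e5, n_coord_up = 0, n_coord_down = 0, seed = 1)
  seg <- plan_segmentation(plan)
  cls <- classify_shift(
    compartment_call_from_labels(plan$binning, rep("A", 4)),
    compartment_call_from_labels(plan$binning, rep("A", 4), condition = "KD"))
  W <- matrix(5, 4, 4)
  D <- matrix(-1, 4, 4)
  D[1, 2] <- D[2, 1] <- 2
  D[3, 4] <- D[4, 3] <- 4
  diag(D) <- 0
  K <- W + D
  res <- intra_inter_differential(toy_cm(W, 1e5, norm = "depth"),
                                  toy_cm(K, 1e5, norm = "depth"), seg, cls)
  expect_equal(res$value[res$type == "intra"], 3)    # (2 + 4) / 2
  expect_equal(res$value[res$type == "inter"], -1)
  # identical matrices: all zero
  res0 <- intra_inter_differential(toy_cm(W, 1e5, norm = "depth"),
                                   toy_cm(W, 1e5, norm = "depth"), seg, cls)
  expect_true(all(res0$value == 0))
})

test_that("intra/inter differential equals a brute-force pair loop", {
  plan <- genome_plan(chrom_lengths = c(chr1 = 4e6), bin_size = 1e5,
                      tad_bp = 1e6, seed = 15)
  pair <- balanced_pair(plan)
  truth <- plan_truth(plan)
  wt_call <- compartment_call_from_labels(plan$binning, truth$bins$comp_wt)
  kd_call <- compartment_call_from_labels(plan$binning, truth$bins$comp_kd,
                                          condition = "KD")
  cls <- classify_shift(wt_call, kd_call)
  seg <- plan_segmentation(plan)
  res <- intra_inter_differential(pair$wt, pair$kd, seg, cls)
  # brute force
  D <- pair$kd$mats[[1]] - pair$wt$mats[[1]]
  n <- nrow(D)
  tad_of <- findInterval(seq_len(n) - 1L, seg$tads$start_bin)
  lab <- truth$bins$comp_wt
  acc <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (is.na(D[i, j])) next
    type <- if (tad_of[i] == tad_of[j]) "intra" else "inter"
    comp <- if (lab[i] == lab[j]) paste0(lab[i], "-", lab[j]) else "A-B"
    key <- paste(type, comp)
    acc[[key]] <- c(acc[[key]], D[i, j])
  }
  for (r in seq_len(nrow(res))) {
    key <- paste(res$type[r], res$compartments[r])
    expect_equal(res$value[r], mean(acc[[key]]), tolerance = 1e-12)
    expect_equal(res$n[r], length(acc[[key]]))
  }
})

test_that("KD intra-TAD gains appear in both compartment classes", {
  plan <- tad_recovery_plan(6)
  pair <- list(wt = cached("tad_wt_6",
                           balance(normalize_depth(simulate_hic(plan, "WT")))),
               kd = balance(normalize_depth(simulate_hic(plan, "KD"))))
  truth <- plan_truth(plan)
  cls <- classify_shift(
    compartment_call_from_labels(plan$binning, truth$bins$comp_wt),
    compartment_call_from_labels(plan$binning, truth$bins$comp_kd,
                                 condition = "KD"))
  seg <- plan_segmentation(plan)
  res <- intra_inter_differential(pair$wt, pair$kd, seg, cls)
  for (cc in c("A-A", "B-B")) {
    v <- res$value[res$type == "intra" & res$compartments == cc]
    expect_gt(mean(v), 0)
  }
})

test_that("rebinned segmentations collapse borders consistently", {
  plan <- tad_recovery_plan(6)
  seg <- plan_segmentation(plan)
  r <- rebin_segmentation(seg, 2)
  expect_equal(r$binning$bin_size, 1e5)
  expect_equal(r$borders$bin, seg$borders$bin %/% 2)
  expect_equal(r$tads$start_bin[1], 0)
  expect_equal(r$tads$end_bin[nrow(r$tads)], r$binning$n_bins[1])
})
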
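#' Pipeline configuration
#'
#' Bundles the simulation plan (or input file paths), resolutions,
#' thresholds and the output directory for [run_pipeline()]. Defaults
#' mirror the study design: TADs at the native resolution, compartments
#' and D-score at 100 kb, a 2 Mb D-score window, FC 1.4 / adjusted p 0.05
#' DE thresholds, 100 kb border-match tolerance and 10,000 permutations.
#'
#' @param plan a [genome_plan] (the simulated-input mode; file inputs can
#'   be loaded with the reader functions and driven through the stage
#'   functions directly).
#' @param outdir output directory.
#' @param comp_binsize compartment/D-score resolution (bp); must be a
#'   multiple of the plan's bin size.
#' @param target_sum per-chromosome depth target.
#' @param dscore_window_bp D-score window half-width.
#' @param fc_thresh,p_thresh DE thresholds.
#' @param border_tol_bp border-match tolerance.
#' @param delta_threshold compartment-shift dPC1 threshold (`NULL` =
#'   chromosome-adaptive default).
#' @param n_perm permutations for the coordination test.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(plan = genome_plan(), outdir = tempfile("tadshift_"),
                            comp_binsize = 100e3, target_sum = 1e6,
                            dscore_window_bp = 2e6,
                            fc_thresh = 1.4, p_thresh = 0.05,
                            border_tol_bp = 100e3, delta_threshold = NULL,
                            n_perm = 10000, seed = plan$seed) {
  stopifnot(inherits(plan, "genome_plan"))
  if (comp_binsize %% plan$binning$bin_size != 0)
    stop("comp_binsize must be a multiple of the plan bin size")
  if (plan$binning$bin_size > comp_binsize)
    stop("TAD resolution must not exceed the compartment resolution")
  if (dscore_window_bp < comp_binsize) stop("D-score window below bin size")
  if (fc_thresh <= 0 || p_thresh <= 0 || p_thresh > 1 || n_perm < 1)
    stop("threshold out of range")
  structure(list(plan = plan, outdir = outdir, comp_binsize = comp_binsize,
                 target_sum = target_sum, dscore_window_bp = dscore_window_bp,
                 fc_thresh = fc_thresh, p_thresh = p_thresh,
                 border_tol_bp = border_tol_bp,
                 delta_threshold = delta_threshold,
                 n_perm = n_perm, seed = seed),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE, scientific = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulate -> depth-normalize and balance -> decay contrast ->
#' compartments and shift classification -> TADs, border strengths and
#' matching -> D-score and track correlations -> track aggregation,
#' G-band classification, variant clustering, H1-ratio TAD groups,
#' accessibility -> gene/TAD expression classes and the coordination
#' permutation test. All stage outputs are plain text (TSV/bedGraph/BED/
#' JSON) under `config$outdir`, listed with md5 checksums in
#' `manifest.json`. Reruns with the same seed are byte-identical.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  plan <- config$plan
  stages <- list()

  # 1. simulate
  sim <- simulate_study(plan)
  write_contact_matrix(sim$wt, file.path(outdir, "matrices"), "WT", "coo")
  write_contact_matrix(sim$kd, file.path(outdir, "matrices"), "KD", "coo")
  for (nm in names(sim$tracks))
    write_bedgraph(sim$tracks[[nm]],
                   file.path(outdir, paste0("track_", gsub("[^A-Za-z0-9_]", "_", nm), ".bedGraph")))
  write_genes(sim$genes, file.path(outdir, "genes.bed"))
  jsonlite::write_json(
    list(bins = sim$truth$bins, borders = sim$truth$borders,
         coord_tads = sim$truth$coord_tads,
         variant_couplings = as.list(sim$truth$variant_couplings)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages$simulate <- list(n_bins = n_bins_total(plan$binning),
                          n_genes = nrow(sim$genes))

  # 2. normalize + decay
  wt_n <- balance(normalize_depth(sim$wt, config$target_sum))
  kd_n <- balance(normalize_depth(sim$kd, config$target_sum))
  dec_wt <- expected_by_distance(wt_n)
  dec_kd <- expected_by_distance(kd_n)
  ctr <- decay_contrast(dec_wt, dec_kd)
  .write_tsv(data.frame(distance_bp = dec_wt$distance_bp, wt = dec_wt$mean,
                        kd = dec_kd$mean, log2_ratio = ctr$per_distance$log2_ratio),
             file.path(outdir, "decay.tsv"))
  stages$normalize <- list(target_sum = config$target_sum,
                           mean_log2_below = ctr$mean_log2_below,
                           mean_log2_above = ctr$mean_log2_above)

  # 3. compartments (at comp_binsize)
  factor <- as.integer(config$comp_binsize / plan$binning$bin_size)
  wt_c <- if (factor > 1) rebin(wt_n, factor) else wt_n
  kd_c <- if (factor > 1) rebin(kd_n, factor) else kd_n
  gc_c <- if (factor > 1) {
    agg <- aggregate_track(sim$tracks$GC, bins_df(wt_c$binning))
    binned_track(wt_c$binning, agg$mean, "GC", "GC-fraction")
  } else sim$tracks$GC
  call_wt <- call_compartments(observed_over_expected(wt_c), gc_c)
  call_kd <- call_compartments(observed_over_expected(kd_c), gc_c)
  cls <- classify_shift(call_wt, call_kd, config$delta_threshold)
  .write_tsv(cls$bins, file.path(outdir, "compartment_shift.tsv"))
  h1_2_sub <- input_subtract(sim$tracks$H1.2, sim$tracks$input)
  h1x_sub <- input_subtract(sim$tracks$H1X, sim$tracks$input)
  shift_sum <- shift_summary_by_chromosome(cls, h1_2_sub)
  .write_tsv(shift_sum$per_chrom, file.path(outdir, "shift_by_chromosome.tsv"))
  expr_cat <- expression_by_category(cls, sim$genes)
  .write_tsv(expr_cat$per_category, file.path(outdir, "expression_by_category.tsv"))
  stages$compartments <- list(
    pct_unchanged = 100 * mean(cls$bins$category %in% c("AA", "BB", "AA+A",
                                                        "AA-A", "BB+B", "BB-B")),
    kruskal_p = expr_cat$kruskal_p)

  # 4. TADs (native resolution)
  seg_wt <- border_strength(wt_n, segment_tads(wt_n))
  seg_kd <- border_strength(kd_n, segment_tads(kd_n),
                            offset = seg_wt$strength_offset)
  bm <- match_borders(seg_wt, seg_kd, config$border_tol_bp)
  dyn <- border_strength_dynamics(bm, seg_wt, seg_kd)
  .write_tsv(seg_wt$tads, file.path(outdir, "tads_wt.tsv"))
  .write_tsv(seg_kd$tads, file.path(outdir, "tads_kd.tsv"))
  .write_tsv(seg_wt$borders, file.path(outdir, "borders_wt.tsv"))
  .write_tsv(seg_kd$borders, file.path(outdir, "borders_kd.tsv"))
  .write_tsv(bm$matches, file.path(outdir, "border_match.tsv"))
  .write_tsv(dyn, file.path(outdir, "border_dynamics.tsv"))
  seg_c <- if (factor > 1) rebin_segmentation(seg_wt, factor) else seg_wt
  iid <- intra_inter_differential(wt_c, kd_c, seg_c, cls)
  .write_tsv(iid, file.path(outdir, "intra_inter_differential.tsv"))
  stages$tads <- list(n_tads_wt = nrow(seg_wt$tads),
                      n_tads_kd = nrow(seg_kd$tads),
                      density_wt = seg_wt$density, density_kd = seg_kd$density,
                      pct_conserved = 100 * mean(bm$matches$category == "conserved"))

  # 5. D-score
  dsc <- compute_dscore(wt_c, kd_c, config$dscore_window_bp)
  write_bedgraph(dsc, file.path(outdir, "dscore.bedGraph"))
  agg_bins <- bins_df(wt_c$binning)
  h1_2_c <- binned_track(wt_c$binning, aggregate_track(h1_2_sub, agg_bins)$mean)
  h1x_c <- binned_track(wt_c$binning, aggregate_track(h1x_sub, agg_bins)$mean)
  cor_h12 <- correlate_with_track(dsc, h1_2_c)
  cor_h1x <- correlate_with_track(dsc, h1x_c)
  .write_tsv(data.frame(track = c("H1.2", "H1X"),
                        spearman = c(cor_h12$estimate, cor_h1x$estimate),
                        p = c(cor_h12$p, cor_h1x$p)),
             file.path(outdir, "dscore_correlations.tsv"))
  stages$dscore <- list(cor_h1_2 = cor_h12$estimate, cor_h1x = cor_h1x$estimate)

  # 6. tracks
  bands <- classify_gbands(plan$bands, sim$tracks$GC)
  .write_tsv(bands, file.path(outdir, "gbands.tsv"))
  variants <- names(plan$couplings)
  band_mat <- do.call(rbind, lapply(variants, function(v)
    aggregate_track(input_subtract(sim$tracks[[v]], sim$tracks$input),
                    bands)$mean))
  rownames(band_mat) <- variants
  clus <- cluster_variant_profiles(band_mat)
  groups_df <- data.frame(variant = names(clus$groups), group = clus$groups)
  .write_tsv(groups_df, file.path(outdir, "variant_clusters.tsv"))
  hg <- h1_ratio_groups(seg_wt$tads[, c("chrom", "start_bp", "end_bp")] |>
                          stats::setNames(c("chrom", "start", "end")),
                        h1_2_sub, h1x_sub)
  acc <- accessibility_change(sim$peaks_wt, sim$peaks_kd,
                              hg[, c("chrom", "start", "end")], groups = hg$group)
  .write_tsv(cbind(hg, acc_diff = acc$per_interval$diff),
             file.path(outdir, "tad_h1_groups.tsv"))
  stages$tracks <- list(n_bands = nrow(bands),
                        cluster_sizes = as.integer(table(clus$groups)))

  # 7. TAD expression + coordination
  statuses <- classify_de(sim$genes, config$fc_thresh, config$p_thresh)
  mapping <- assign_genes_to_tads(sim$genes, seg_wt)
  tsum <- classify_tads(mapping, statuses, seg_wt)
  .write_tsv(tsum, file.path(outdir, "tad_classes.tsv"))
  coord <- permutation_null(sim$genes, seg_wt, n_perm = config$n_perm,
                            seed = config$seed + 701L)
  jsonlite::write_json(
    list(observed = coord$observed, expected = coord$expected,
         ratio = coord$ratio, chisq = coord$chisq, df = coord$df, p = coord$p,
         n_perm = coord$n_perm, seed = coord$seed),
    file.path(outdir, "coordination.json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)
  tad_iv <- seg_wt$tads
  cov_df <- data.frame(
    h1_2 = aggregate_track(h1_2_sub, stats::setNames(
      tad_iv[, c("chrom", "start_bp", "end_bp")], c("chrom", "start", "end")))$mean,
    gene_density = {
      ids <- paste0(tad_iv$chrom, ":", unlist(lapply(
        rle(tad_iv$chrom)$lengths, seq_len)))
      cnt <- table(mapping$tad)
      as.numeric(cnt[ids]) / ((tad_iv$end_bp - tad_iv$start_bp) / 1e6)
    })
  cov_df$gene_density[is.na(cov_df$gene_density)] <- 0
  ids <- paste0(tad_iv$chrom, ":", unlist(lapply(rle(tad_iv$chrom)$lengths, seq_len)))
  gsum <- summarize_tad_groups(tsum$class[match(ids, tsum$tad)], cov_df)
  .write_tsv(gsum$summary, file.path(outdir, "tad_group_summary.tsv"))
  xtab <- tad_compartment_crosstab(tsum, seg_wt, cls)
  stages$tad_expression <- list(
    classes = lapply(as.list(table(tsum$class)), as.integer),
    coordination_p = coord$p, crosstab_p = xtab$chisq_p)

  # manifest
  files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("tadshift")),
    seed = config$seed,
    parameters = list(comp_binsize = config$comp_binsize,
                      target_sum = config$target_sum,
                      dscore_window_bp = config$dscore_window_bp,
                      fc_thresh = config$fc_thresh, p_thresh = config$p_thresh,
                      border_tol_bp = config$border_tol_bp,
                      n_perm = config$n_perm),
    stages = stages,
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(outdir, f)))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, decay = ctr, calls = list(wt = call_wt, kd = call_kd),
                 shift = cls, seg = list(wt = seg_wt, kd = seg_kd),
                 border_match = bm, dscore = dsc,
                 correlations = list(h1_2 = cor_h12, h1x = cor_h1x),
                 clusters = clus, tad_classes = tsum, coordination = coord,
                 manifest = manifest, outdir = outdir))
}
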
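#' Classify differential expression status per gene
#'
#' `up` if `FC >= fc_thresh` and `padj <= p_thresh`; `down` if
#' `FC <= 1/fc_thresh` and `padj <= p_thresh`; otherwise `unchanged`.
#' Fold-changes are linear (KD/WT).
#'
#' @param genes a `gene_table` with `fc` and `padj`.
#' @param fc_thresh linear fold-change threshold (default 1.4).
#' @param p_thresh adjusted p-value threshold (default 0.05).
#' @return character vector of per-gene statuses.
#' @export
classify_de <- function(genes, fc_thresh = 1.4, p_thresh = 0.05) {
  if (fc_thresh <= 0 || p_thresh <= 0) stop("thresholds must be positive")
  if (any(genes$fc <= 0)) stop("fold-changes must be positive")
  ifelse(genes$fc >= fc_thresh & genes$padj <= p_thresh, "up",
         ifelse(genes$fc <= 1 / fc_thresh & genes$padj <= p_thresh, "down",
                "unchanged"))
}

#' Assign genes to TADs
#'
#' Each gene goes to the unique TAD containing its transcription start site
#' (strand-aware; `mode = "majority"` instead assigns by the TAD covering
#' most of the gene body). TAD identifiers are `chrom:index`.
#'
#' @param genes a `gene_table`.
#' @param seg a `tad_segmentation`.
#' @param mode `"tss"` (default) or `"majority"`.
#' @return `genes` with an added `tad` column.
#' @export
assign_genes_to_tads <- function(genes, seg, mode = c("tss", "majority")) {
  mode <- match.arg(mode)
  genes$tad <- NA_character_
  for (chrom in unique(genes$chrom)) {
    i <- match(chrom, seg$binning$chrom)
    if (is.na(i)) stop("gene chromosome not in segmentation: ", chrom)
    chrom_len <- seg$binning$length[i]
    sel <- genes$chrom == chrom
    if (any(genes$end[sel] > chrom_len))
      stop("gene beyond chromosome end on ", chrom)
    td <- seg$tads[seg$tads$chrom == chrom, ]
    pos <- if (mode == "tss") tss_of(genes[sel, ]) else NULL
    if (mode == "majority") {
      # midpoint of the overlap-dominant TAD equals the TAD covering the
      # gene midpoint for a partition
      pos <- floor((genes$start[sel] + genes$end[sel]) / 2)
    }
    idx <- findInterval(pos, td$start_bp)
    genes$tad[sel] <- paste0(chrom, ":", idx)
  }
  genes
}

#' Classify TADs by the expression response of their genes
#'
#' `Up`: at least one up-regulated gene and none down; `Dw`: at least one
#' down and none up; `UpDw`: both directions present; `Control`: no
#' deregulated genes. TADs in `seg` with no assigned genes are reported as
#' Control with `n_genes = 0` and flagged.
#'
#' @param mapping genes with a `tad` column ([assign_genes_to_tads()]).
#' @param statuses per-gene statuses ([classify_de()]).
#' @param seg optional `tad_segmentation` used to include gene-less TADs.
#' @return data.frame of class `tad_expression_summary`: per TAD gene/up/
#'   down counts, proportion of genes with FC > 1, and class.
#' @export
classify_tads <- function(mapping, statuses, seg = NULL) {
  stopifnot(length(statuses) == nrow(mapping))
  tad <- mapping$tad
  up <- tapply(statuses == "up", tad, sum)
  dw <- tapply(statuses == "down", tad, sum)
  n <- tapply(statuses, tad, length)
  prop_up <- tapply(mapping$fc > 1, tad, mean)
  out <- data.frame(tad = names(n), n_genes = as.integer(n),
                    n_up = as.integer(up), n_down = as.integer(dw),
                    prop_fc_up = as.numeric(prop_up), empty = FALSE)
  if (!is.null(seg)) {
    all_tads <- unlist(lapply(seg$binning$chrom, function(ch) {
      k <- sum(seg$tads$chrom == ch)
      paste0(ch, ":", seq_len(k))
    }))
    missing <- setdiff(all_tads, out$tad)
    if (length(missing))
      out <- rbind(out, data.frame(tad = missing, n_genes = 0L, n_up = 0L,
                                   n_down = 0L, prop_fc_up = NA_real_,
                                   empty = TRUE))
  }
  out$class <- with(out, ifelse(n_up > 0 & n_down == 0, "Up",
                         ifelse(n_down > 0 & n_up == 0, "Dw",
                         ifelse(n_up > 0 & n_down > 0, "UpDw", "Control"))))
  rownames(out) <- NULL
  class(out) <- c("tad_expression_summary", "data.frame")
  out
}

#' Histogram of per-TAD proportions of genes with positive fold-change
#'
#' Only TADs with at least `min_genes` genes are eligible. Proportions are
#' binned into [0,0.1), ..., [0.9,1] (1 included in the top bin).
#'
#' @param mapping genes with a `tad` column.
#' @param min_genes minimum genes per eligible TAD.
#' @return list: `counts` (length-10 named vector), `per_tad` data.frame,
#'   `n_eligible`.
#' @export
coordination_histogram <- function(mapping, min_genes = 4) {
  n <- tapply(mapping$fc, mapping$tad, length)
  up <- tapply(mapping$fc > 1, mapping$tad, sum)
  eligible <- n >= min_genes
  if (!any(eligible)) stop("no TADs with at least ", min_genes, " genes")
  prop <- as.numeric(up[eligible] / n[eligible])
  counts <- tabulate(pmin(floor(prop * 10) + 1L, 10L), nbins = 10L)
  names(counts) <- paste0(seq(0, 0.9, 0.1), "-", seq(0.1, 1, 0.1))
  list(counts = counts,
       per_tad = data.frame(tad = names(n)[eligible],
                            n_genes = as.integer(n[eligible]),
                            prop_fc_up = prop),
       n_eligible = sum(eligible))
}

# histogram counts for arbitrary TSS positions, vectorized for permutations
.hist_from_positions <- function(tss, chrom_idx, fc_up, tad_breaks, tad_offset,
                                 n_tads_total, min_genes) {
  tad_global <- integer(length(tss))
  for (ci in seq_along(tad_breaks))
    tad_global[chrom_idx == ci] <-
      tad_offset[ci] + findInterval(tss[chrom_idx == ci], tad_breaks[[ci]])
  n <- tabulate(tad_global, nbins = n_tads_total)
  u <- tabulate(tad_global[fc_up], nbins = n_tads_total)
  eligible <- n >= min_genes
  prop <- u[eligible] / n[eligible]
  tabulate(pmin(floor(prop * 10) + 1L, 10L), nbins = 10L)
}

#' Permutation null for coordinated expression within TADs
#'
#' Randomizes gene locations `n_perm` times, constraining each gene to its
#' own chromosome, preserving gene lengths and forbidding overlap (uniform
#' placement over the valid non-overlapping configurations via a spacings
#' sampler), carrying each gene's fold-change along. The coordination
#' histogram is recomputed each time; the expected histogram is the mean
#' over permutations, and observed counts are compared to expected counts
#' with a Pearson chi-square over populated bins (adjacent bins with
#' expected count < 1 are pooled).
#'
#' @param genes a `gene_table`.
#' @param seg a `tad_segmentation`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param min_genes minimum genes per eligible TAD.
#' @return object of class `coordination_result`: observed and expected
#'   histograms, per-bin obs/exp ratio, chi-square statistic, df and p,
#'   `n_perm`, `seed`.
#' @export
permutation_null <- function(genes, seg, n_perm = 10000, seed = 1,
                             min_genes = 4) {
  chroms <- unique(genes$chrom)
  chrom_idx <- match(genes$chrom, chroms)
  lens <- genes$end - genes$start
  chrom_len <- seg$binning$length[match(chroms, seg$binning$chrom)]
  tad_breaks <- lapply(chroms, function(ch)
    seg$tads$start_bp[seg$tads$chrom == ch])
  n_per_chrom <- vapply(tad_breaks, length, 1L)
  tad_offset <- c(0L, cumsum(n_per_chrom))[seq_along(chroms)]
  n_tads_total <- sum(n_per_chrom)
  fc_up <- genes$fc > 1

  mapping <- assign_genes_to_tads(genes, seg)
  obs <- coordination_histogram(mapping, min_genes = min_genes)$counts

  exp_mat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      tss <- numeric(nrow(genes))
      for (ci in seq_along(chroms)) {
        sel <- chrom_idx == ci
        starts <- place_nonoverlap(lens[sel], chrom_len[ci])
        # TSS at the placed start; strand is irrelevant under the null
        tss[sel] <- starts
      }
      .hist_from_positions(tss, chrom_idx, fc_up, tad_breaks, tad_offset,
                           n_tads_total, min_genes)
    }, numeric(10))
  })
  expected <- rowMeans(exp_mat)
  ratio <- ifelse(expected > 0, obs / expected, NA_real_)

  # pool adjacent bins until each pooled group has expected >= 1
  grp <- integer(10); g <- 1L; acc <- 0
  for (b in 1:10) {
    grp[b] <- g
    acc <- acc + expected[b]
    if (acc >= 1 && b < 10) { g <- g + 1L; acc <- 0 }
  }
  if (acc < 1 && g > 1) grp[grp == g] <- g - 1L   # fold a light tail back
  obs_g <- tapply(obs, grp, sum)
  exp_g <- tapply(expected, grp, sum)
  keep <- exp_g > 0
  chisq <- sum((obs_g[keep] - exp_g[keep])^2 / exp_g[keep])
  df <- max(sum(keep) - 1L, 1L)
  structure(list(observed = obs, expected = expected, ratio = ratio,
                 chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE),
                 n_perm = n_perm, seed = seed, min_genes = min_genes),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("coordination_result: chi-square %.2f on %d df, p = %.3g (%d permutations)\n",
              x$chisq, x$df, x$p, x$n_perm))
  invisible(x)
}

#' Summarize TAD groups over covariates
#'
#' For each TAD group (e.g. the Control/Up/Dw/UpDw classes or coordination
#' deciles), reports per-covariate medians, a Kruskal-Wallis test across
#' groups and per-group Mann-Whitney tests against the pooled remaining
#' groups.
#'
#' @param groups per-TAD group labels.
#' @param covariates data.frame of per-TAD covariates (same row order).
#' @return list: `summary` (group x covariate medians and p-values),
#'   `kruskal` (per covariate).
#' @export
summarize_tad_groups <- function(groups, covariates) {
  g <- factor(groups)
  summ <- do.call(rbind, lapply(names(covariates), function(cv) {
    x <- covariates[[cv]]
    do.call(rbind, lapply(levels(g), function(lev) {
      a <- x[g == lev]; b <- x[g != lev]
      data.frame(covariate = cv, group = lev, n = sum(g == lev),
                 median = stats::median(a, na.rm = TRUE),
                 mw_p = if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2)
                   suppressWarnings(stats::wilcox.test(a, b)$p.value)
                 else NA_real_)
    }))
  }))
  kr <- do.call(rbind, lapply(names(covariates), function(cv) {
    x <- covariates[[cv]]
    ok <- !is.na(x)
    data.frame(covariate = cv,
               kruskal_p = if (nlevels(droplevels(g[ok])) >= 2)
                 stats::kruskal.test(x[ok], droplevels(g[ok]))$p.value
               else NA_real_)
  }))
  list(summary = summ, kruskal = kr)
}

#' Cross-tabulate TAD classes against compartment-shift categories
#'
#' Each TAD takes the majority shift category of its bins; the table of
#' TAD class by category is tested with a Pearson chi-square.
#'
#' @param summary a `tad_expression_summary` (with `tad` and `class`).
#' @param seg the `tad_segmentation` the summary was built on.
#' @param cls a `shift_classification` (any binning on the same genome).
#' @return list: `table` (class x category counts), `chisq_p`.
#' @export
tad_compartment_crosstab <- function(summary, seg, cls) {
  cat_of_tad <- vapply(seq_len(nrow(summary)), function(r) {
    parts <- strsplit(summary$tad[r], ":", fixed = TRUE)[[1]]
    chrom <- parts[1]; k <- as.integer(parts[2])
    td <- seg$tads[seg$tads$chrom == chrom, ][k, ]
    sel <- cls$bins$chrom == chrom & cls$bins$start >= td$start_bp &
      cls$bins$start < td$end_bp & cls$bins$category != "masked"
    if (!any(sel)) return(NA_character_)
    names(which.max(table(cls$bins$category[sel])))
  }, character(1))
  ok <- !is.na(cat_of_tad)
  tab <- table(class = summary$class[ok], category = cat_of_tad[ok])
  p <- if (nrow(tab) >= 2 && ncol(tab) >= 2)
    suppressWarnings(stats::chisq.test(tab)$p.value) else NA_real_
  list(table = tab, chisq_p = p)
}
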
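#' Call A/B compartments from an observed/expected matrix
#'
#' Per chromosome: Pearson correlation matrix of the O/E contact profiles
#' (masked bins dropped), principal component analysis, and selection of
#' PC1 or PC2 by the larger absolute Pearson correlation with the GC track.
#' The chosen component is oriented so that its correlation with GC is
#' positive; bins with positive oriented values are labeled A, negative B.
#' Chromosomes whose best GC correlation is below `confidence_threshold`
#' are flagged low-confidence; chromosomes with fewer than 10 unmasked
#' bins are masked entirely with a warning.
#'
#' @param oe an O/E [contact_matrix] (see [observed_over_expected()]).
#' @param gc a GC [track] on the same binning.
#' @param confidence_threshold minimum |cor(PC, GC)| below which a
#'   chromosome's call is flagged low-confidence.
#' @return object of class `compartment_call`: `bins` (per-bin `chrom`,
#'   `start`, `end`, `bin`, `pc1`, `label` in A/B/masked) and `chrom_meta`
#'   (chosen component, orientation sign, GC correlation, confidence flag).
#' @export
call_compartments <- function(oe, gc, confidence_threshold = 0.2) {
  stopifnot(inherits(oe, "contact_matrix"))
  if (!identical(unique(gc$chrom), oe$binning$chrom) ||
      nrow(gc) != n_bins_total(oe$binning))
    stop("GC track is not on the matrix binning")
  bins <- bins_df(oe$binning)
  bins$pc1 <- NA_real_
  bins$label <- "masked"
  meta <- list()
  for (i in seq_along(oe$binning$chrom)) {
    chrom <- oe$binning$chrom[i]
    mat <- oe$mats[[i]]
    n <- nrow(mat)
    off <- oe$binning$offset[i]
    keep <- which(colSums(!is.na(mat)) > 1)
    if (length(keep) < 10) {
      warning("chromosome ", chrom, " has fewer than 10 unmasked bins; masked")
      meta[[chrom]] <- data.frame(chrom = chrom, component = NA_integer_,
                                  sign = NA_real_, gc_cor = NA_real_,
                                  low_confidence = TRUE, masked = TRUE)
      next
    }
    sub <- mat[keep, keep, drop = FALSE]
    cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cm[!is.finite(cm)] <- 0
    pca <- stats::prcomp(cm, center = TRUE, scale. = FALSE)
    gc_vals <- gc$value[off + keep]
    ncomp <- min(2L, ncol(pca$x))
    cors <- vapply(seq_len(ncomp), function(k)
      suppressWarnings(stats::cor(pca$x[, k], gc_vals)), numeric(1))
    cors[is.na(cors)] <- 0
    comp <- which.max(abs(cors))
    sgn <- if (cors[comp] >= 0) 1 else -1
    pc <- sgn * pca$x[, comp]
    bins$pc1[off + keep] <- pc
    bins$label[off + keep] <- ifelse(pc > 0, "A", ifelse(pc < 0, "B", "A"))
    meta[[chrom]] <- data.frame(chrom = chrom, component = comp, sign = sgn,
                                gc_cor = abs(cors[comp]),
                                low_confidence = abs(cors[comp]) < confidence_threshold,
                                masked = FALSE)
  }
  structure(list(bins = bins, chrom_meta = do.call(rbind, meta),
                 binning = oe$binning, condition = oe$condition,
                 oriented = TRUE),
            class = "compartment_call")
}

#' Build a compartment call from known labels
#'
#' Constructs an oriented `compartment_call` directly from per-bin A/B
#' labels (and optionally PC values), e.g. from planted truth, so that the
#' shift classifier can be exercised independently of the PCA caller.
#'
#' @param binning a [genome_binning].
#' @param labels per-bin labels in `A`/`B`/`masked`.
#' @param pc1 optional per-bin component values; defaults to +1/-1 by label.
#' @param condition condition label.
#' @return a `compartment_call`.
#' @export
compartment_call_from_labels <- function(binning, labels, pc1 = NULL,
                                         condition = "WT") {
  bins <- bins_df(binning)
  if (length(labels) != nrow(bins)) stop("need one label per bin")
  if (is.null(pc1)) pc1 <- ifelse(labels == "A", 1, ifelse(labels == "B", -1, NA))
  bins$pc1 <- ifelse(labels == "masked", NA_real_, pc1)
  bins$label <- labels
  structure(list(bins = bins, chrom_meta = NULL, binning = binning,
                 condition = condition, oriented = TRUE),
            class = "compartment_call")
}

#' Classify per-bin compartment changes into eight categories
#'
#' Bins whose label changes are `A-to-B` / `B-to-A`. Same-label bins are
#' sub-classified by the PC1 change `dPC1 = PC1_kd - PC1_wt`: A bins with
#' `dPC1 > thr` decompact (`AA+A`), `< -thr` compact (`AA-A`), else `AA`;
#' B bins with `dPC1 < -thr` compact (`BB+B`, more negative = more B),
#' `> thr` decompact (`BB-B`), else `BB`. The default threshold is 20% of
#' the chromosome-wise WT PC1 standard deviation.
#'
#' @param wt,kd oriented `compartment_call`s on identical binnings.
#' @param delta_threshold absolute dPC1 threshold; `NULL` for the
#'   chromosome-wise default.
#' @return object of class `shift_classification`: per-bin data.frame with
#'   `category` plus WT/KD PC1 and labels, and the thresholds used.
#' @export
classify_shift <- function(wt, kd, delta_threshold = NULL) {
  if (!isTRUE(wt$oriented) || !isTRUE(kd$oriented))
    stop("compartment calls must be oriented")
  if (!same_binning(wt$binning, kd$binning)) stop("binning mismatch")
  b <- wt$bins[, c("chrom", "start", "end", "bin")]
  b$pc1_wt <- wt$bins$pc1
  b$pc1_kd <- kd$bins$pc1
  b$label_wt <- wt$bins$label
  b$label_kd <- kd$bins$label
  thr <- if (is.null(delta_threshold)) {
    sds <- tapply(b$pc1_wt, b$chrom, stats::sd, na.rm = TRUE)
    0.2 * unname(sds[b$chrom])
  } else rep(delta_threshold, nrow(b))
  d <- b$pc1_kd - b$pc1_wt
  cat_of <- function(lw, lk, d, thr) {
    if (lw == "masked" || lk == "masked" || is.na(d)) return("masked")
    if (lw == "A" && lk == "B") return("A-to-B")
    if (lw == "B" && lk == "A") return("B-to-A")
    if (lw == "A") {
      if (d > thr) return("AA+A")
      if (d < -thr) return("AA-A")
      return("AA")
    }
    if (d < -thr) return("BB+B")
    if (d > thr) return("BB-B")
    "BB"
  }
  b$category <- mapply(cat_of, b$label_wt, b$label_kd, d, thr)
  b$dpc1 <- d
  structure(list(bins = b, delta_threshold = thr, binning = wt$binning),
            class = "shift_classification")
}

#' Per-chromosome compartment-shift summary against an H1 track
#'
#' Percentage of bins changing compartment (A-to-B or B-to-A) per
#' chromosome, the chromosome's mean H1 signal, and the Spearman
#' correlation between the two across chromosomes (reported missing when
#' fewer than 3 chromosomes or a degenerate ranking).
#'
#' @param cls a `shift_classification`.
#' @param h1_track a [track] on the same binning.
#' @return list with `per_chrom` data.frame and `spearman` (rho, p, n).
#' @export
shift_summary_by_chromosome <- function(cls, h1_track) {
  b <- cls$bins
  h1 <- h1_track$value
  per <- do.call(rbind, lapply(unique(b$chrom), function(ch) {
    sel <- b$chrom == ch & b$category != "masked"
    data.frame(chrom = ch,
               pct_changed = if (any(sel))
                 100 * mean(b$category[sel] %in% c("A-to-B", "B-to-A")) else NA_real_,
               mean_h1 = mean(h1[b$chrom == ch], na.rm = TRUE))
  }))
  sp <- list(rho = NA_real_, p = NA_real_, n = nrow(per))
  ok <- stats::complete.cases(per[, c("pct_changed", "mean_h1")])
  if (sum(ok) >= 3 &&
      stats::sd(per$pct_changed[ok]) > 0 && stats::sd(per$mean_h1[ok]) > 0) {
    ct <- suppressWarnings(stats::cor.test(per$pct_changed[ok], per$mean_h1[ok],
                                           method = "spearman"))
    sp <- list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  list(per_chrom = per, spearman = sp)
}

# strand-aware TSS (0-based position)
tss_of <- function(genes) ifelse(genes$strand == "-", genes$end - 1, genes$start)

#' Expression change by compartment-shift category
#'
#' Maps genes to bins by TSS, averages log2 fold-changes per bin, and for
#' each shift category reports the per-bin distribution, a one-sample
#' Wilcoxon signed-rank test against the global median, and a
#' Kruskal-Wallis test across categories.
#'
#' @param cls a `shift_classification`.
#' @param genes a `gene_table`.
#' @return list with `per_category` data.frame (`category`, `n`,
#'   `median_l2fc`, `wilcoxon_p`), `kruskal_p`, and the per-bin table.
#' @export
expression_by_category <- function(cls, genes) {
  b <- cls$bins
  tss <- tss_of(genes)
  bin_of <- rep(NA_integer_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- genes$chrom == ch
    rows <- which(b$chrom == ch)
    idx <- findInterval(tss[sel], b$start[rows])
    bin_of[sel] <- ifelse(idx >= 1 & idx <= length(rows), rows[idx], NA)
  }
  l2fc <- log2(genes$fc)
  ok <- !is.na(bin_of)
  per_bin_val <- rowsum(l2fc[ok], bin_of[ok]) / rowsum(rep(1, sum(ok)), bin_of[ok])
  per_bin <- data.frame(bin_row = as.integer(rownames(per_bin_val)),
                        l2fc = per_bin_val[, 1])
  per_bin$category <- b$category[per_bin$bin_row]
  per_bin <- per_bin[per_bin$category != "masked", ]
  global_med <- stats::median(per_bin$l2fc)
  cats <- c("AA", "BB", "A-to-B", "B-to-A", "AA+A", "AA-A", "BB+B", "BB-B")
  per_category <- do.call(rbind, lapply(cats, function(cc) {
    x <- per_bin$l2fc[per_bin$category == cc]
    data.frame(category = cc, n = length(x),
               median_l2fc = if (length(x)) stats::median(x) else NA_real_,
               wilcoxon_p = if (length(x) >= 2)
                 suppressWarnings(stats::wilcox.test(x, mu = global_med)$p.value)
               else NA_real_)
  }))
  pops <- per_bin$category[per_bin$category %in% cats]
  kruskal_p <- if (length(unique(pops)) >= 2)
    stats::kruskal.test(per_bin$l2fc, factor(per_bin$category))$p.value
  else NA_real_
  list(per_category = per_category, kruskal_p = kruskal_p, per_bin = per_bin)
}
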
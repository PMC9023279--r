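#' Binned signal track
#'
#' A per-interval scalar signal (ChIP coverage, GC fraction, ATAC, D-score,
#' ...) stored as a sorted, non-overlapping interval table with 0-based
#' half-open coordinates.
#'
#' @param chrom,start,end interval coordinates.
#' @param value per-interval signal, finite or `NA` (masked).
#' @param name track name.
#' @param units one of `"RPM"`, `"input-subtracted"`, `"GC-fraction"`,
#'   `"score"`.
#' @return data.frame of class `genomic_track`.
#' @export
track <- function(chrom, start, end, value, name = "track", units = "score") {
  units <- match.arg(units, c("RPM", "input-subtracted", "GC-fraction", "score"))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   value = value)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  if (any(df$end <= df$start)) stop("intervals must have positive width")
  by_chrom <- split(df, df$chrom)
  for (b in by_chrom)
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("track intervals overlap on ", b$chrom[1])
  if (any(is.infinite(df$value))) stop("track values must be finite or NA")
  rownames(df) <- NULL
  attr(df, "name") <- name
  attr(df, "units") <- units
  class(df) <- c("genomic_track", "data.frame")
  df
}

#' Build a track on a genome binning
#'
#' @param binning a [genome_binning].
#' @param values one value per global bin.
#' @inheritParams track
#' @return a [track].
#' @export
binned_track <- function(binning, values, name = "track", units = "score") {
  b <- bins_df(binning)
  if (length(values) != nrow(b)) stop("need one value per bin")
  track(b$chrom, b$start, b$end, values, name = name, units = units)
}

#' Read/write 4-column bedGraph
#'
#' Plain-text bedGraph (`chrom start end value`, 0-based half-open); track
#' lines are not used.
#'
#' @param path file path.
#' @param name,units stored on the returned [track].
#' @return `read_bedgraph`: a [track]; `write_bedgraph`: the path, invisibly.
#' @export
read_bedgraph <- function(path, name = basename(path), units = "score") {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  track(df$chrom, df$start, df$end, df$value, name = name, units = units)
}

#' @param x a [track].
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path) {
  df <- as.data.frame(x)[, c("chrom", "start", "end", "value")]
  df$value <- format(df$value, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

track_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Subtract input coverage from a ChIP track
#'
#' Elementwise `chip - input` on identical interval grids; both tracks are
#' expected in reads-per-million.
#'
#' @param chip,input [track]s on identical intervals.
#' @return a [track] with units `"input-subtracted"`.
#' @export
input_subtract <- function(chip, input) {
  if (!identical(chip$chrom, input$chrom) ||
      !isTRUE(all.equal(chip$start, input$start)) ||
      !isTRUE(all.equal(chip$end, input$end)))
    stop("chip and input tracks are on different intervals")
  track(chip$chrom, chip$start, chip$end, chip$value - input$value,
        name = paste0(attr(chip, "name"), "_minus_input"),
        units = "input-subtracted")
}

#' Length-weighted mean of a track over intervals
#'
#' Each query interval receives the bp-weighted mean of the track values it
#' overlaps (an interval covering part of a bin receives that fraction of
#' the bin). Intervals with no overlap get `NA`.
#'
#' @param x a [track].
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return `intervals` with an added `mean` column.
#' @export
aggregate_track <- function(x, intervals) {
  q <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1L, intervals$end))
  s <- track_gr(x)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  out <- intervals
  out$mean <- NA_real_
  if (length(hits)) {
    ov <- IRanges::pintersect(q[S4Vectors::queryHits(hits)],
                              s[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    v <- x$value[S4Vectors::subjectHits(hits)]
    qi <- S4Vectors::queryHits(hits)
    ok <- !is.na(v)
    num <- rowsum((w * v)[ok], qi[ok])
    den <- rowsum(w[ok], qi[ok])
    idx <- as.integer(rownames(num))
    out$mean[idx] <- num[, 1] / den[, 1]
  }
  out
}

#' Classify Giemsa bands, splitting unstained bands by GC quartile
#'
#' Positively stained bands keep their stain class (Gpos25..Gpos100).
#' Unstained (gneg) bands are split into four equal-size groups by GC
#' content: Gneg1 = highest-GC quartile down to Gneg4 = lowest. Ties at a
#' quartile boundary go to the lower-index (higher-GC) group.
#'
#' @param bands data.frame with `chrom`, `start`, `end`, `stain`
#'   (`gpos25|gpos50|gpos75|gpos100|gneg`).
#' @param gc a GC-fraction [track].
#' @return `bands` with added `gc` and `class` columns.
#' @export
classify_gbands <- function(bands, gc) {
  stopifnot(all(bands$stain %in% c("gpos25", "gpos50", "gpos75", "gpos100", "gneg")))
  bands <- aggregate_track(gc, bands)
  names(bands)[names(bands) == "mean"] <- "gc"
  bands$class <- NA_character_
  pos <- bands$stain != "gneg"
  bands$class[pos] <- sub("^g", "G", bands$stain[pos])
  neg <- which(!pos)
  if (length(neg) < 4) stop("need at least 4 gneg bands to form GC quartiles")
  r <- rank(-bands$gc[neg], ties.method = "min")
  grp <- ceiling(4 * r / length(neg))
  bands$class[neg] <- paste0("Gneg", grp)
  bands
}

#' Group TADs by their H1.2/H1X balance
#'
#' Ranks TADs by the difference of per-TAD mean input-subtracted H1.2 and
#' H1X signal (a log-ratio surrogate that tolerates the negative values
#' input subtraction produces) and splits them into `n_groups` equal-size
#' groups; Group 1 has the lowest H1.2 relative to H1X.
#'
#' @param tads data.frame with `chrom`, `start`, `end` (one row per TAD).
#' @param h1_2,h1x input-subtracted [track]s.
#' @param n_groups number of groups.
#' @param mode `"difference"` (default) or `"log2_ratio"` (requires strictly
#'   positive per-TAD means).
#' @return `tads` with `h1_2`, `h1x`, `ratio` and integer `group` columns.
#' @export
h1_ratio_groups <- function(tads, h1_2, h1x, n_groups = 4,
                            mode = c("difference", "log2_ratio")) {
  mode <- match.arg(mode)
  if (n_groups > nrow(tads)) stop("n_groups exceeds the number of TADs")
  tads$h1_2 <- aggregate_track(h1_2, tads)$mean
  tads$h1x <- aggregate_track(h1x, tads)$mean
  tads$ratio <- if (mode == "difference") tads$h1_2 - tads$h1x else {
    if (any(tads$h1_2 <= 0 | tads$h1x <= 0, na.rm = TRUE))
      stop("log2_ratio mode requires strictly positive per-TAD means")
    log2(tads$h1_2 / tads$h1x)
  }
  r <- rank(tads$ratio, ties.method = "first")
  tads$group <- ceiling(n_groups * r / nrow(tads))
  tads
}

#' Hierarchically cluster H1-variant abundance profiles
#'
#' Standardizes each variant's profile (z-score across intervals; rows with
#' zero variance are left unscaled with a warning), clusters with Euclidean
#' distance and complete linkage, and cuts the tree into two groups.
#'
#' @param abundance numeric matrix, variants in rows, intervals in columns.
#' @return list with `hclust` (the row dendrogram) and `groups` (named
#'   integer vector of the 2-group cut).
#' @export
cluster_variant_profiles <- function(abundance) {
  if (nrow(abundance) < 2 || ncol(abundance) < 2)
    stop("need at least 2 variants and 2 intervals")
  z <- t(apply(abundance, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("zero-variance profile left unscaled")
      v - mean(v)
    } else (v - mean(v)) / s
  }))
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "complete")
  list(hclust = hc, groups = stats::cutree(hc, k = 2))
}

#' Accessibility change over intervals
#'
#' Per interval and condition, either the ATAC peak density (peaks per Mb;
#' when peak tables are supplied) or the mean coverage (when tracks are
#' supplied), plus the KD - WT difference. If `groups` is given, group
#' medians, a Kruskal-Wallis test and per-group Mann-Whitney tests against
#' the remaining intervals are reported.
#'
#' @param atac_wt,atac_kd [track]s, or data.frames of peak intervals
#'   (`chrom`, `start`, `end`).
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param groups optional per-interval group labels.
#' @return list with `per_interval` (intervals plus `wt`, `kd`, `diff`) and,
#'   when `groups` is given, `group_summary` and `kruskal_p`.
#' @export
accessibility_change <- function(atac_wt, atac_kd, intervals, groups = NULL) {
  measure <- function(a) {
    if (inherits(a, "genomic_track")) return(aggregate_track(a, intervals)$mean)
    q <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start + 1L, intervals$end))
    p <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
    GenomicRanges::countOverlaps(q, p) / ((intervals$end - intervals$start) / 1e6)
  }
  out <- intervals
  out$wt <- measure(atac_wt)
  out$kd <- measure(atac_kd)
  out$diff <- out$kd - out$wt
  res <- list(per_interval = out)
  if (!is.null(groups)) {
    g <- factor(groups)
    res$group_summary <- do.call(rbind, lapply(levels(g), function(lev) {
      x <- out$diff[g == lev]
      y <- out$diff[g != lev]
      data.frame(group = lev, n = length(x), median_diff = stats::median(x, na.rm = TRUE),
                 mw_p = if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2)
                   suppressWarnings(stats::wilcox.test(x, y)$p.value)
                 else NA_real_)
    }))
    res$kruskal_p <- if (nlevels(g) >= 2)
      stats::kruskal.test(out$diff, g)$p.value else NA_real_
  }
  res
}
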
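# --- segment statistics -----------------------------------------------------
# Within-segment pair sums/counts via 2D prefix sums on the (symmetric) O/E
# matrix with NA and the diagonal zeroed. pair_sum(a,b) is over unordered
# pairs i<j with a <= i,j <= b.

.prefix2d <- function(x) {
  n <- nrow(x)
  P <- matrix(0, n + 1L, n + 1L)
  P[-1L, -1L] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  P
}

# gain of modelling segment [a,b] with its own mean versus the chromosome
# background mean, in units of the shared-variance Gaussian log-likelihood:
# gain = n_ab * (mean_ab - mu0)^2 / (2 sigma0^2)
.chrom_seg_stats <- function(oe_mat, band = Inf) {
  n <- nrow(oe_mat)
  x <- oe_mat
  diag(x) <- NA
  if (is.finite(band)) x[abs(row(x) - col(x)) > band] <- NA
  vals <- x[upper.tri(x)]
  vals <- vals[!is.na(vals)]
  mu0 <- mean(vals)
  s20 <- stats::var(vals)
  if (!is.finite(s20) || s20 <= 0) s20 <- 1
  X0 <- x; X0[is.na(X0)] <- 0
  C0 <- (!is.na(x)) * 1
  Ps <- .prefix2d(X0)
  Pc <- .prefix2d(C0)
  av <- rep(seq_len(n), n)          # segment start a (rows)
  bv <- rep(seq_len(n), each = n)   # segment end b (cols)
  block <- function(P) P[cbind(bv + 1L, bv + 1L)] - P[cbind(av, bv + 1L)] -
    P[cbind(bv + 1L, av)] + P[cbind(av, av)]
  S <- matrix(block(Ps) / 2, n, n)
  N <- matrix(block(Pc) / 2, n, n)
  G <- matrix(0, n, n)
  pos <- N > 0
  G[pos] <- N[pos] * (S[pos] / N[pos] - mu0)^2 / (2 * s20)
  G[lower.tri(G)] <- 0   # only a <= b meaningful
  list(gain = G, n_pairs = length(vals), mu0 = mu0, s20 = s20)
}

# dynamic programming over segment partitions maximizing
# sum(gain) - n_borders * penalty, all segments >= min_size bins.
# Returns 1-based segment start positions of the optimal partition.
.dp_segment <- function(gain, penalty, min_size = 3L, max_tads = NULL,
                        start_penalty = NULL) {
  n <- nrow(gain)
  if (n < 2L * min_size) return(1L)
  if (is.null(start_penalty)) start_penalty <- numeric(n)
  if (is.null(max_tads)) {
    best <- c(0, rep(-Inf, n))       # best[j+1] = best objective of prefix 1..j
    arg <- integer(n)
    for (j in seq_len(n)) {
      if (j < min_size) next
      a <- seq_len(j - min_size + 1L)
      vals <- best[a] + gain[cbind(a, rep(j, length(a)))] -
        (penalty + start_penalty[a]) * (a > 1L)
      k <- which.max(vals)
      best[j + 1L] <- vals[k]
      arg[j] <- a[k]
    }
    starts <- integer(0)
    j <- n
    while (j >= 1L) {
      starts <- c(arg[j], starts)
      j <- arg[j] - 1L
    }
    return(starts)
  }
  K <- min(max_tads, n %/% min_size)
  best <- matrix(-Inf, K, n)  # best[k, j]: gain sum of prefix 1..j in k segments
  arg <- matrix(0L, K, n)
  js <- seq_len(n)
  best[1, js >= min_size] <- gain[1, js[js >= min_size]]
  arg[1, js >= min_size] <- 1L
  if (K >= 2) for (k in 2:K) {
    for (j in seq.int(k * min_size, n)) {
      a <- seq.int((k - 1L) * min_size + 1L, j - min_size + 1L)
      vals <- best[k - 1L, a - 1L] + gain[cbind(a, rep(j, length(a)))] -
        start_penalty[a]
      i <- which.max(vals)
      best[k, j] <- vals[i]
      arg[k, j] <- a[i]
    }
  }
  obj <- best[, n] - (seq_len(K) - 1L) * penalty
  kbest <- which.max(obj)
  starts <- integer(kbest)
  j <- n
  for (k in seq.int(kbest, 1L)) {
    starts[k] <- arg[k, j]
    j <- arg[k, j] - 1L
  }
  starts
}

.objective_of <- function(gain, starts, n, penalty) {
  ends <- c(starts[-1] - 1L, n)
  sum(gain[cbind(starts, ends)]) - (length(starts) - 1L) * penalty
}

#' Segment a chromosome into TADs by BIC-penalized breakpoint detection
#'
#' Converts the matrix to observed/expected, then finds the partition of
#' each chromosome into contiguous segments maximizing the summed
#' segment-mean Gaussian log-likelihood gain over a chromosome-wide
#' background mean, minus a BIC penalty of `0.5 * log(n_pairs)` per border
#' (`n_pairs` = unmasked off-diagonal pairs). Segments model within-TAD
#' enrichment with one mean parameter each and a shared variance; pairs
#' spanning segments keep the background mean, so the objective is additive
#' and is maximized exactly by dynamic programming. The likelihood is
#' restricted to pairs within `band_bp` of the diagonal: domain structure
#' lives at sub-megabase to few-megabase separations, and long-range pairs
#' only add variance that drowns the segment signal. The segmentation is a
#' full partition of the chromosome.
#'
#' @param m a normalized (ideally balanced) [contact_matrix].
#' @param max_tads optional cap on the number of TADs per chromosome.
#' @param min_size minimum TAD size in bins.
#' @param band_bp maximum pair separation (bp) entering the likelihood.
#' @return object of class `tad_segmentation`: `tads` (chrom, start_bin,
#'   end_bin, start_bp, end_bp), `borders` (chrom, bin, bp, strength = NA
#'   until [border_strength()] is run), per-chromosome `objective`, and the
#'   genome-wide `density` score.
#' @export
segment_tads <- function(m, max_tads = NULL, min_size = 3L, band_bp = 5e6) {
  oe <- if (m$norm == "oe") m else observed_over_expected(m)
  band <- max(round(band_bp / m$binning$bin_size), 2 * min_size)
  tads <- list(); borders <- list()
  objective <- numeric(0)
  for (i in seq_along(m$binning$chrom)) {
    chrom <- m$binning$chrom[i]
    n <- m$binning$n_bins[i]
    st <- .chrom_seg_stats(oe$mats[[i]], band)
    penalty <- 0.5 * log(max(st$n_pairs, 2))
    starts <- if (n < 2L * min_size) 1L
      else .dp_segment(st$gain, penalty, min_size, max_tads)
    ends <- c(starts[-1] - 1L, n)
    tads[[chrom]] <- data.frame(
      chrom = chrom,
      start_bin = starts - 1L, end_bin = ends,      # 0-based half-open
      start_bp = (starts - 1L) * m$binning$bin_size,
      end_bp = pmin(ends * m$binning$bin_size, m$binning$length[i]))
    bb <- starts[-1] - 1L
    borders[[chrom]] <- if (length(bb))
      data.frame(chrom = chrom, bin = bb, bp = bb * m$binning$bin_size,
                 strength = NA_real_)
    else NULL
    objective[chrom] <- .objective_of(st$gain, starts, n, penalty)
  }
  seg <- structure(list(
    tads = do.call(rbind, unname(tads)),
    borders = if (length(Filter(Negate(is.null), borders)))
      do.call(rbind, unname(Filter(Negate(is.null), borders)))
    else data.frame(chrom = character(), bin = integer(), bp = numeric(),
                    strength = numeric()),
    binning = m$binning, condition = m$condition,
    objective = objective, min_size = min_size, max_tads = max_tads,
    band = band),
    class = "tad_segmentation")
  seg$density <- density_score(m, seg)
  rownames(seg$tads) <- NULL
  rownames(seg$borders) <- NULL
  seg
}

#' @export
print.tad_segmentation <- function(x, ...) {
  cat(sprintf("tad_segmentation [%s]: %d TADs, %d borders, density %.3f\n",
              x$condition, nrow(x$tads), nrow(x$borders),
              if (is.finite(x$density)) x$density else NA))
  invisible(x)
}

#' Score border robustness by repeated degradation of the optimal path
#'
#' Assigns each border of the optimal segmentation an integer strength in
#' 1..`rounds` (10 by default). The score of the optimal border path is
#' degraded in `rounds` steps of one fixed offset unit each; at step `r` a
#' border is retained while its marginal contribution to the objective -
#' the loss from removing it and merging its two flanking segments -
#' still matches the accumulated reduction `r * offset`. The strength is
#' the number of steps the border survives, floored at 1, so 10 marks
#' borders that withstand every degradation and 1 borders present only in
#' the undegraded optimum. By default the offset unit is sized per
#' chromosome so that the ladder spans the path's marginal-gain range (the
#' strongest border sets the scale and scores 10). When comparing
#' strengths across conditions, compute them on one condition first and
#' pass its `$strength_offset` as `offset` for the other so both are on
#' the same scale.
#'
#' @param m the [contact_matrix] `seg` was computed from.
#' @param seg a [segment_tads()] result.
#' @param rounds number of degradation steps.
#' @param offset offset unit: `NULL` (per-chromosome auto-scale), a single
#'   number, or a vector named by chromosome.
#' @return `seg` with the `strength` column of `$borders` filled in and
#'   the per-chromosome offset units in `$strength_offset`.
#' @export
border_strength <- function(m, seg, rounds = 10L, offset = NULL) {
  if (rounds < 1) stop("rounds must be >= 1")
  oe <- if (m$norm == "oe") m else observed_over_expected(m)
  seg$borders$strength <- NA_real_
  seg$strength_offset <- stats::setNames(rep(NA_real_, length(m$binning$chrom)),
                                         m$binning$chrom)
  for (i in seq_along(m$binning$chrom)) {
    chrom <- m$binning$chrom[i]
    n <- m$binning$n_bins[i]
    sel <- seg$borders$chrom == chrom
    if (!any(sel)) next
    st <- .chrom_seg_stats(oe$mats[[i]], seg$band)
    penalty <- 0.5 * log(max(st$n_pairs, 2))
    orig_borders <- seg$borders$bin[sel]
    nodes <- c(1L, orig_borders + 1L, n + 1L)
    nb <- length(orig_borders)
    g <- st$gain[cbind(nodes[seq_len(nb + 1L)], nodes[-1] - 1L)]
    merged <- st$gain[cbind(nodes[seq_len(nb)], nodes[-(1:2)] - 1L)]
    marg <- g[seq_len(nb)] + g[-1] - merged - penalty
    off <- if (is.null(offset)) max(marg) / rounds
           else if (!is.null(names(offset))) unname(offset[chrom])
           else offset
    seg$strength_offset[chrom] <- off
    strength <- if (isTRUE(off > 0))
      colSums(outer(seq_len(rounds), marg, function(r, mg) mg >= r * off))
    else rep(0, nb)
    seg$borders$strength[sel] <- pmin(pmax(strength, 1L), rounds)
  }
  seg
}

#' TAD density score
#'
#' Ratio of the summed contact values with both bins inside a common TAD to
#' the summed values spanning different TADs (cis pairs only, diagonal
#' excluded). `Inf` when there are no inter-TAD pairs.
#'
#' @param m a [contact_matrix].
#' @param seg a `tad_segmentation` on the same binning.
#' @return a single number.
#' @export
density_score <- function(m, seg) {
  within <- 0; across <- 0
  for (i in seq_along(m$binning$chrom)) {
    chrom <- m$binning$chrom[i]
    mat <- m$mats[[i]]
    n <- nrow(mat)
    td <- seg$tads[seg$tads$chrom == chrom, ]
    tad_of <- findInterval(seq_len(n) - 1L, td$start_bin)
    same <- outer(tad_of, tad_of, "==")
    up <- upper.tri(mat)
    within <- within + sum(mat[up & same], na.rm = TRUE)
    across <- across + sum(mat[up & !same], na.rm = TRUE)
  }
  if (across == 0) return(Inf)
  within / across
}

#' Match TAD borders between conditions
#'
#' Greedy nearest matching of WT borders to KD borders within a tolerance
#' (ties broken toward the leftward KD border; each KD border used at most
#' once). Exact matches are `conserved`, matches at 1..tol bins are
#' `shifted`, unmatched WT borders `non-conserved`; unmatched KD borders
#' are reported as de novo.
#'
#' @param wt,kd `tad_segmentation`s on the same binning.
#' @param tol_bp matching tolerance in bp (default 100 kb).
#' @return object of class `border_match`: `matches` (per WT border:
#'   category, matched KD bin, offset in bins) and `de_novo` (KD-only
#'   borders).
#' @export
match_borders <- function(wt, kd, tol_bp = 100e3) {
  if (!same_binning(wt$binning, kd$binning)) stop("binning mismatch")
  tol <- floor(tol_bp / wt$binning$bin_size)
  out <- list(); dn <- list()
  for (chrom in wt$binning$chrom) {
    wb <- wt$borders[wt$borders$chrom == chrom, ]
    kb <- kd$borders[kd$borders$chrom == chrom, ]
    used <- rep(FALSE, nrow(kb))
    if (nrow(wb)) {
      wb$category <- "non-conserved"
      wb$kd_bin <- NA_integer_
      wb$offset <- NA_integer_
      for (r in seq_len(nrow(wb))) {
        if (!nrow(kb)) break
        d <- kb$bin - wb$bin[r]
        cand <- which(!used & abs(d) <= tol)
        if (!length(cand)) next
        cand <- cand[order(abs(d[cand]), kb$bin[cand])]   # ties -> leftward
        j <- cand[1]
        used[j] <- TRUE
        wb$kd_bin[r] <- kb$bin[j]
        wb$offset[r] <- d[j]
        wb$category[r] <- if (d[j] == 0L) "conserved" else "shifted"
      }
      out[[chrom]] <- wb
    }
    if (nrow(kb) && any(!used)) dn[[chrom]] <- kb[!used, ]
  }
  structure(list(
    matches = if (length(out)) do.call(rbind, unname(out))
    else data.frame(chrom = character(), bin = integer(), bp = numeric(),
                    strength = numeric(), category = character(),
                    kd_bin = integer(), offset = integer()),
    de_novo = if (length(dn)) do.call(rbind, unname(dn))
    else data.frame(chrom = character(), bin = integer(), bp = numeric(),
                    strength = numeric()),
    tol_bins = tol), class = "border_match")
}

#' Border-strength dynamics by conservation category
#'
#' For conserved and shifted borders, compares WT strengths with the
#' strengths of their matched KD borders; non-conserved WT borders are
#' compared against the pooled de novo KD borders. Mann-Whitney p-values
#' are reported (missing for categories with fewer than 2 borders on
#' either side).
#'
#' @param match a [match_borders()] result.
#' @param wt,kd `tad_segmentation`s with strengths computed.
#' @return data.frame: category, n, mean WT and KD strength, p value.
#' @export
border_strength_dynamics <- function(match, wt, kd) {
  if (any(is.na(wt$borders$strength)) || any(is.na(kd$borders$strength)))
    stop("run border_strength() on both segmentations first")
  mm <- match$matches
  kd_strength <- function(chrom, bin) {
    kb <- kd$borders
    kb$strength[match(paste(chrom, bin), paste(kb$chrom, kb$bin))]
  }
  rows <- lapply(c("conserved", "shifted", "non-conserved"), function(cc) {
    sel <- mm$category == cc
    if (!any(sel)) return(data.frame(category = cc, n = 0L,
                                     mean_wt = NA_real_, mean_kd = NA_real_,
                                     p = NA_real_))
    ws <- mm$strength[sel]
    ks <- if (cc == "non-conserved") match$de_novo$strength
          else kd_strength(mm$chrom[sel], mm$kd_bin[sel])
    data.frame(category = cc, n = sum(sel),
               mean_wt = mean(ws),
               mean_kd = if (length(ks)) mean(ks) else NA_real_,
               p = if (sum(sel) >= 2 && length(ks) >= 2)
                 suppressWarnings(stats::wilcox.test(ws, ks)$p.value)
               else NA_real_)
  })
  do.call(rbind, rows)
}

#' Coarsen a TAD segmentation to a larger bin size
#'
#' Divides border bins by `factor` (rounding down) and rebuilds the TAD
#' intervals; duplicate borders collapse.
#'
#' @param seg a `tad_segmentation`.
#' @param factor positive integer.
#' @return a `tad_segmentation` on the coarsened binning.
#' @export
rebin_segmentation <- function(seg, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(seg)
  lengths <- stats::setNames(seg$binning$length, seg$binning$chrom)
  nb <- genome_binning(lengths, seg$binning$bin_size * factor)
  tads <- list(); borders <- list()
  for (i in seq_along(nb$chrom)) {
    chrom <- nb$chrom[i]
    n <- nb$n_bins[i]
    bb <- sort(unique(seg$borders$bin[seg$borders$chrom == chrom] %/% factor))
    bb <- bb[bb > 0 & bb < n]
    starts <- c(0L, bb)
    ends <- c(bb, n)
    tads[[chrom]] <- data.frame(chrom = chrom, start_bin = starts, end_bin = ends,
                                start_bp = starts * nb$bin_size,
                                end_bp = pmin(ends * nb$bin_size, nb$length[i]))
    if (length(bb))
      borders[[chrom]] <- data.frame(chrom = chrom, bin = bb,
                                     bp = bb * nb$bin_size, strength = NA_real_)
  }
  structure(list(tads = do.call(rbind, unname(tads)),
                 borders = if (length(borders)) do.call(rbind, unname(borders))
                 else data.frame(chrom = character(), bin = integer(),
                                 bp = numeric(), strength = numeric()),
                 binning = nb, condition = seg$condition,
                 objective = NULL, min_size = seg$min_size,
                 max_tads = seg$max_tads, density = NA_real_),
            class = "tad_segmentation")
}

#' Differential intra- and inter-TAD interactions by compartment
#'
#' For every cis bin pair, the KD - WT difference is classed as intra- or
#' inter-TAD (WT segmentation) and by the WT compartment labels of its two
#' bins (A-A, B-B, A-B), then summarized per chromosome as the mean
#' difference per pair (`mode = "mean"`) or the number of pairs whose
#' absolute difference exceeds `count_threshold` (`mode = "count"`).
#'
#' @param wt_m,kd_m [contact_matrix]es depth-normalized to a common target,
#'   same binning.
#' @param wt_seg `tad_segmentation` on the same binning (rebin first if
#'   called at a coarser resolution; see [rebin_segmentation()]).
#' @param cls a `shift_classification` providing WT labels.
#' @param mode `"mean"` or `"count"`.
#' @param count_threshold threshold for `mode = "count"`.
#' @return data.frame: chrom, type (intra/inter), compartments, n pairs,
#'   value.
#' @export
intra_inter_differential <- function(wt_m, kd_m, wt_seg, cls,
                                     mode = c("mean", "count"),
                                     count_threshold = 0) {
  mode <- match.arg(mode)
  if (!same_binning(wt_m$binning, kd_m$binning) ||
      !same_binning(wt_m$binning, wt_seg$binning) ||
      !same_binning(wt_m$binning, cls$binning))
    stop("binning mismatch")
  rows <- list()
  for (i in seq_along(wt_m$binning$chrom)) {
    chrom <- wt_m$binning$chrom[i]
    D <- kd_m$mats[[i]] - wt_m$mats[[i]]
    n <- nrow(D)
    td <- wt_seg$tads[wt_seg$tads$chrom == chrom, ]
    tad_of <- findInterval(seq_len(n) - 1L, td$start_bin)
    lab <- cls$bins$label_wt[cls$bins$chrom == chrom]
    up <- which(upper.tri(D), arr.ind = TRUE)
    di <- D[up]
    li <- lab[up[, 1]]; lj <- lab[up[, 2]]
    ok <- !is.na(di) & li != "masked" & lj != "masked"
    type <- ifelse(tad_of[up[, 1]] == tad_of[up[, 2]], "intra", "inter")
    compart <- ifelse(li == lj, paste0(li, "-", lj), "A-B")
    grp <- paste(type, compart, sep = "|")[ok]
    di <- di[ok]
    val <- if (mode == "mean") tapply(di, grp, mean)
           else tapply(abs(di) > count_threshold, grp, sum)
    cnt <- tapply(di, grp, length)
    parts <- strsplit(names(val), "|", fixed = TRUE)
    rows[[chrom]] <- data.frame(
      chrom = chrom,
      type = vapply(parts, `[`, "", 1),
      compartments = vapply(parts, `[`, "", 2),
      n = as.integer(cnt), value = as.numeric(val))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
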
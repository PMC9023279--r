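#' Synthetic study plan with planted genome structure
#'
#' Builds a fully materialized plan for a two-condition (WT vs H1 KD)
#' synthetic study: a toy genome with planted A/B compartment blocks, tiled
#' TADs with per-TAD insulation, condition effects (compartment flips,
#' intra-TAD gain, long-range gain, optional localized gain regions), a
#' banded GC model with GC-coupled H1-variant tracks, and genes whose
#' fold-changes are coordinated within designated TADs. All random choices
#' made at plan time (flipped blocks, band GC means, coordinated TADs) are
#' drawn from `seed`, so the same arguments always produce the same plan.
#'
#' Contact intensity for bins i, j at distance `d` bins (diagonal treated as
#' d = 1) is
#' `depth * d^-alpha * c_ij * t_ij * g_ij` with `c_ij = 1 +/- epsilon` for
#' same/different planted compartment, `t_ij = 1 + tau` within a TAD
#' (times `1 + delta` in KD), and `g_ij = 1 + gamma` in KD beyond `s_star_bp`.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_size bin width (bp).
#' @param alpha distance-decay exponent, > 0.
#' @param epsilon compartment contrast in [0, 1).
#' @param comp_block_bp width of alternating A/B compartment blocks.
#' @param flip_fraction fraction of bins whose compartment flips in KD
#'   (applied at block granularity); scalar or named per chromosome.
#' @param tad_bp TAD width used to tile each chromosome.
#' @param tau per-TAD insulation depth (>= 0); recycled over all TADs.
#' @param delta intra-TAD gain in KD.
#' @param gamma long-range gain in KD beyond `s_star_bp`.
#' @param s_star_bp distance threshold for the long-range gain.
#' @param depth expected contact count at distance 1 bin, named per
#'   condition or scalar.
#' @param local_gain optional `list(regions = data.frame(chrom,start,end),
#'   factor = )`: KD contacts with both bins inside a region are multiplied
#'   by `factor`.
#' @param band_bp Giemsa-band width for the GC model.
#' @param gc_chrom_offset per-chromosome GC offset (scalar or named).
#' @param comp_gc_delta GC elevation of A over B bins (half-difference).
#' @param gc_noise_sd per-bin GC noise SD.
#' @param couplings named vector of GC couplings for the H1 variants.
#' @param h3k9me3_coupling,atac_coupling GC couplings of the other tracks.
#' @param track_noise_sd Gaussian noise SD of ChIP tracks.
#' @param input_level,input_noise_sd mean and noise SD of the input track.
#' @param atac_gain_base,atac_gain_gc KD accessibility gain: uniform part
#'   and part proportional to positive GC z-score.
#' @param genes_per_tad Poisson mean of genes per TAD.
#' @param gene_length min/max gene length (bp).
#' @param fc_log2_sd SD of null log2 fold-changes.
#' @param n_coord_up,n_coord_down number of coordinated TADs per direction.
#' @param coord_low_gc if `TRUE`, coordinated TADs are drawn from the
#'   lowest-GC (H1.2-richest) quartile of TADs instead of uniformly.
#' @param coord_effect planted log2 fold-change shift in coordinated TADs.
#' @param coord_genes gene count forced in each coordinated TAD.
#' @param padj_alt_shape Beta(shape, 1) shape for adjusted p-values of genes
#'   in coordinated TADs (null genes draw Uniform(0, 1)).
#' @param atac_peak_rate,atac_peak_gain base ATAC peaks per bin and KD gain
#'   in high-GC bins.
#' @param seed RNG seed for the whole plan.
#' @return an object of class `genome_plan`.
#' @export
genome_plan <- function(chrom_lengths = c(chr1 = 20e6, chr2 = 20e6),
                        bin_size = 100e3,
                        alpha = 1, epsilon = 0.3,
                        comp_block_bp = 1e6,
                        flip_fraction = 0.1,
                        tad_bp = 1e6, tau = 1.0,
                        delta = 0.3, gamma = 0.3, s_star_bp = 30e6,
                        depth = c(WT = 100, KD = 100),
                        local_gain = NULL,
                        band_bp = 2e6,
                        gc_chrom_offset = 0,
                        comp_gc_delta = 0.02,
                        gc_noise_sd = 0.01,
                        couplings = c(H1.2 = -1.0, H1.5 = -0.8, H1.0 = -0.6,
                                      H1.4 = 0.7, H1X = 1.0),
                        h3k9me3_coupling = -0.5,
                        atac_coupling = 0.8,
                        track_noise_sd = 0.5,
                        input_level = 1, input_noise_sd = 0.1,
                        atac_gain_base = 0.2, atac_gain_gc = 0.3,
                        genes_per_tad = 5,
                        gene_length = c(5e3, 3e4),
                        fc_log2_sd = 0.5,
                        n_coord_up = 2, n_coord_down = 2,
                        coord_low_gc = FALSE,
                        coord_effect = 1.0,
                        coord_genes = 8,
                        padj_alt_shape = 0.05,
                        atac_peak_rate = 2, atac_peak_gain = 2,
                        seed = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (length(depth) == 1 && is.null(names(depth))) depth <- c(WT = unname(depth), KD = unname(depth))
  if (any(depth <= 0)) stop("sequencing depth must be positive")
  if (any(c(tau, delta, gamma) < 0) || any(!is.finite(c(tau, delta, gamma))))
    stop("rate parameters must be finite and non-negative")
  known <- c("H1.2", "H1.5", "H1.0", "H1.4", "H1X")
  if (!all(names(couplings) %in% known))
    stop("unknown variant name(s): ",
         paste(setdiff(names(couplings), known), collapse = ", "))
  binning <- genome_binning(chrom_lengths, bin_size)

  frac_of <- function(x, chrom) {
    if (length(x) == 1 && is.null(names(x))) return(unname(x))
    if (chrom %in% names(x)) return(unname(x[chrom]))
    0
  }

  plan <- with_seed(seed, {
    comp_wt <- list(); flip <- list(); tads <- list(); bands <- list()
    tau_cursor <- 0L
    for (i in seq_along(binning$chrom)) {
      chrom <- binning$chrom[i]
      n <- binning$n_bins[i]
      # alternating A/B blocks
      block <- max(1L, round(comp_block_bp / bin_size))
      lab <- rep(c("A", "B"), each = block, length.out = n + 2L * block)[seq_len(n)]
      comp_wt[[chrom]] <- lab
      # flip whole blocks until the requested bin fraction is reached
      blk_id <- (seq_len(n) - 1L) %/% block
      target <- frac_of(flip_fraction, chrom) * n
      fl <- rep(FALSE, n)
      if (target > 0) {
        for (b in sample(unique(blk_id))) {
          if (sum(fl) >= target) break
          fl[blk_id == b] <- TRUE
        }
      }
      flip[[chrom]] <- fl
      # TAD tiling
      tw <- max(2L, round(tad_bp / bin_size))
      starts <- seq(0L, n - 1L, by = tw)
      if (length(starts) > 1 && n - starts[length(starts)] < 2L)
        starts <- starts[-length(starts)]     # absorb a 1-bin trailing TAD
      ends <- c(starts[-1], n)
      k <- length(starts)
      tau_vals <- rep(tau, length.out = tau_cursor + k)[tau_cursor + seq_len(k)]
      tau_cursor <- tau_cursor + k
      tads[[chrom]] <- data.frame(start_bin = starts, end_bin = ends, tau = tau_vals)
      # G bands with stain cycle and gneg GC spread
      bw <- band_bp
      bstart <- seq(0, binning$length[i] - 1, by = bw)
      bend <- pmin(bstart + bw, binning$length[i])
      stains <- rep(c("gpos25", "gneg", "gpos50", "gneg",
                      "gpos75", "gneg", "gpos100", "gneg"),
                    length.out = length(bstart))
      gc_mean <- ifelse(stains == "gneg",
                        stats::runif(length(bstart), 0.38, 0.52),
                        c(gpos25 = 0.45, gpos50 = 0.43,
                          gpos75 = 0.41, gpos100 = 0.39)[stains])
      bands[[chrom]] <- data.frame(chrom = chrom, start = bstart, end = bend,
                                   stain = stains,
                                   gc_mean = gc_mean + frac_of(gc_chrom_offset, chrom))
    }
    # coordinated TADs drawn genome-wide (optionally from the low-GC half)
    all_tads <- do.call(rbind, lapply(names(tads), function(ch)
      data.frame(chrom = ch, tad_index = seq_len(nrow(tads[[ch]])))))
    all_tads$gc <- vapply(seq_len(nrow(all_tads)), function(r) {
      ch <- all_tads$chrom[r]
      td <- tads[[ch]][all_tads$tad_index[r], ]
      mid <- (td$start_bin + td$end_bin) / 2 * bin_size
      bd <- bands[[ch]]
      bd$gc_mean[findInterval(mid, bd$start)]
    }, numeric(1))
    n_coord <- n_coord_up + n_coord_down
    coord <- NULL
    if (n_coord > 0) {
      pool <- if (coord_low_gc) {
        q <- max(n_coord, ceiling(nrow(all_tads) / 4))
        order(all_tads$gc)[seq_len(q)]
      } else seq_len(nrow(all_tads))
      if (n_coord > length(pool)) stop("more coordinated TADs than TADs")
      pick <- pool[sample(length(pool), n_coord)]
      coord <- all_tads[pick, c("chrom", "tad_index")]
      coord$direction <- rep(c(1, -1), c(n_coord_up, n_coord_down))
      coord$effect <- coord_effect
      rownames(coord) <- NULL
    }
    list(comp_wt = comp_wt, flip = flip, tads = tads,
         bands = do.call(rbind, bands), coord_tads = coord)
  })

  comp_kd <- lapply(binning$chrom, function(ch) {
    lab <- plan$comp_wt[[ch]]
    fl <- plan$flip[[ch]]
    ifelse(fl, ifelse(lab == "A", "B", "A"), lab)
  })
  names(comp_kd) <- binning$chrom
  rownames(plan$bands) <- NULL

  structure(
    c(plan, list(
      binning = binning, comp_kd = comp_kd,
      alpha = alpha, epsilon = epsilon, delta = delta, gamma = gamma,
      s_star_bp = s_star_bp, depth = depth, local_gain = local_gain,
      comp_gc_delta = comp_gc_delta, gc_noise_sd = gc_noise_sd,
      couplings = couplings, h3k9me3_coupling = h3k9me3_coupling,
      atac_coupling = atac_coupling, track_noise_sd = track_noise_sd,
      input_level = input_level, input_noise_sd = input_noise_sd,
      atac_gain_base = atac_gain_base, atac_gain_gc = atac_gain_gc,
      genes_per_tad = genes_per_tad, gene_length = gene_length,
      fc_log2_sd = fc_log2_sd, coord_effect = coord_effect,
      coord_genes = coord_genes, padj_alt_shape = padj_alt_shape,
      atac_peak_rate = atac_peak_rate, atac_peak_gain = atac_peak_gain,
      seed = seed)),
    class = "genome_plan"
  )
}

#' @export
print.genome_plan <- function(x, ...) {
  cat(sprintf(paste0("genome_plan: %d chromosome(s), %d bins at %s bp; ",
                     "alpha=%.2f epsilon=%.2f delta=%.2f gamma=%.2f seed=%d\n"),
              length(x$binning$chrom), n_bins_total(x$binning),
              format(x$binning$bin_size, big.mark = ","),
              x$alpha, x$epsilon, x$delta, x$gamma, x$seed))
  invisible(x)
}

# per-bin TAD index and tau for one chromosome
.tad_of <- function(plan, chrom) {
  td <- plan$tads[[chrom]]
  n <- chrom_bins(plan$binning, chrom)
  idx <- findInterval(seq_len(n) - 1L, td$start_bin)
  list(index = idx, tau = td$tau[idx])
}

.gain_bins <- function(plan, chrom) {
  n <- chrom_bins(plan$binning, chrom)
  inside <- rep(FALSE, n)
  lg <- plan$local_gain
  if (is.null(lg)) return(inside)
  reg <- lg$regions[lg$regions$chrom == chrom, , drop = FALSE]
  if (!nrow(reg)) return(inside)
  starts <- (seq_len(n) - 1L) * plan$binning$bin_size
  for (r in seq_len(nrow(reg)))
    inside[starts >= reg$start[r] & starts < reg$end[r]] <- TRUE
  inside
}

#' Model contact intensity for a plan
#'
#' The Poisson intensity `lambda_ij` that [simulate_hic()] samples from,
#' useful for checking the sampler and as a noise-free reference.
#'
#' @param plan a [genome_plan].
#' @param condition `"WT"` or `"KD"`.
#' @return named list of per-chromosome intensity matrices.
#' @export
expected_hic_intensity <- function(plan, condition = c("WT", "KD")) {
  condition <- match.arg(condition)
  kd <- condition == "KD"
  labs <- if (kd) plan$comp_kd else plan$comp_wt
  out <- lapply(plan$binning$chrom, function(chrom) {
    n <- chrom_bins(plan$binning, chrom)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    d[d == 0] <- 1
    lab <- labs[[chrom]]
    cmod <- ifelse(outer(lab, lab, "=="), 1 + plan$epsilon, 1 - plan$epsilon)
    tinfo <- .tad_of(plan, chrom)
    same_tad <- outer(tinfo$index, tinfo$index, "==")
    tmod <- matrix(1, n, n)
    tmod[same_tad] <- (1 + outer(tinfo$tau, tinfo$tau, pmin))[same_tad]
    if (kd) tmod[same_tad] <- tmod[same_tad] * (1 + plan$delta)
    gmod <- matrix(1, n, n)
    if (kd && plan$gamma > 0)
      gmod[d * plan$binning$bin_size > plan$s_star_bp] <- 1 + plan$gamma
    lmod <- matrix(1, n, n)
    if (kd && !is.null(plan$local_gain)) {
      inside <- .gain_bins(plan, chrom)
      lmod[outer(inside, inside, "&")] <- plan$local_gain$factor
    }
    unname(plan$depth[condition]) * d^(-plan$alpha) * cmod * tmod * gmod * lmod
  })
  names(out) <- plan$binning$chrom
  out
}

#' Simulate a Hi-C contact matrix
#'
#' Draws symmetric Poisson counts around [expected_hic_intensity()]. The
#' diagonal is simulated with the distance-1 decay value; downstream
#' statistics exclude it. Deterministic given the plan seed and condition.
#'
#' @inheritParams expected_hic_intensity
#' @return a raw [contact_matrix].
#' @export
simulate_hic <- function(plan, condition = c("WT", "KD")) {
  condition <- match.arg(condition)
  lambda <- expected_hic_intensity(plan, condition)
  mats <- with_seed(plan$seed + 17L * match(condition, c("WT", "KD")), {
    lapply(lambda, function(lam) {
      n <- nrow(lam)
      up <- upper.tri(lam, diag = TRUE)
      m <- matrix(0, n, n)
      m[up] <- stats::rpois(sum(up), lam[up])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
  })
  names(mats) <- plan$binning$chrom
  contact_matrix(mats, plan$binning, condition = condition, norm = "raw")
}

# per-bin GC, drawn reproducibly from the plan (band mean + compartment
# elevation + noise); shared by tracks, peaks and truth
.sim_gc <- function(plan) {
  with_seed(plan$seed + 51L, {
    vals <- unlist(lapply(plan$binning$chrom, function(chrom) {
      n <- chrom_bins(plan$binning, chrom)
      starts <- (seq_len(n) - 1L) * plan$binning$bin_size
      bd <- plan$bands[plan$bands$chrom == chrom, ]
      band_of <- findInterval(starts, bd$start)
      gc <- bd$gc_mean[band_of] +
        plan$comp_gc_delta * ifelse(plan$comp_wt[[chrom]] == "A", 1, -1) +
        stats::rnorm(n, 0, plan$gc_noise_sd)
      pmin(pmax(gc, 0.25), 0.65)
    }))
    unname(vals)
  })
}

#' Simulate binned signal tracks
#'
#' Generates the GC track from the plan's band model, an input track, RPM
#' ChIP tracks for the five H1 variants (GC-coupled with the plan's signs:
#' negative for H1.2/H1.5/H1.0, positive for H1.4/H1X), H3K9me3, and ATAC
#' coverage for both conditions (KD gains accessibility, preferentially at
#' high GC). Variant tracks share the input track's baseline so that
#' [input_subtract()] recovers the planted GC-coupled signal.
#'
#' @param plan a [genome_plan].
#' @return named list of [track]s: `GC`, `input`, the H1 variants,
#'   `H3K9me3`, `ATAC_WT`, `ATAC_KD`.
#' @export
simulate_tracks <- function(plan) {
  gc <- .sim_gc(plan)
  zgc <- (gc - mean(gc)) / stats::sd(gc)
  nb <- n_bins_total(plan$binning)
  with_seed(plan$seed + 52L, {
    input <- plan$input_level + stats::rnorm(nb, 0, plan$input_noise_sd)
    out <- list(GC = binned_track(plan$binning, gc, "GC", "GC-fraction"),
                input = binned_track(plan$binning, input, "input", "RPM"))
    for (v in names(plan$couplings))
      out[[v]] <- binned_track(
        plan$binning,
        input + plan$couplings[[v]] * zgc + stats::rnorm(nb, 0, plan$track_noise_sd),
        v, "RPM")
    out$H3K9me3 <- binned_track(
      plan$binning,
      input + plan$h3k9me3_coupling * zgc + stats::rnorm(nb, 0, plan$track_noise_sd),
      "H3K9me3", "RPM")
    atac_wt <- 1 + plan$atac_coupling * zgc + stats::rnorm(nb, 0, 0.3)
    atac_kd <- atac_wt + plan$atac_gain_base +
      plan$atac_gain_gc * pmax(zgc, 0) + stats::rnorm(nb, 0, 0.1)
    out$ATAC_WT <- binned_track(plan$binning, atac_wt, "ATAC_WT", "RPM")
    out$ATAC_KD <- binned_track(plan$binning, atac_kd, "ATAC_KD", "RPM")
    out
  })
}

#' Simulate ATAC peak calls
#'
#' Per-bin Poisson peak counts with a KD gain concentrated in high-GC bins
#' (the open, H1X-rich side of the genome).
#'
#' @inheritParams expected_hic_intensity
#' @return data.frame of peak intervals (`chrom`, `start`, `end`).
#' @export
simulate_atac_peaks <- function(plan, condition = c("WT", "KD")) {
  condition <- match.arg(condition)
  gc <- .sim_gc(plan)
  zgc <- (gc - mean(gc)) / stats::sd(gc)
  rate <- plan$atac_peak_rate +
    if (condition == "KD") plan$atac_peak_gain * (zgc > 0) else 0
  b <- bins_df(plan$binning)
  with_seed(plan$seed + 73L + match(condition, c("WT", "KD")), {
    counts <- stats::rpois(nrow(b), rate)
    idx <- rep(seq_len(nrow(b)), counts)
    width <- 400
    start <- b$start[idx] +
      floor(stats::runif(length(idx)) * pmax(b$end[idx] - b$start[idx] - width, 1))
    data.frame(chrom = b$chrom[idx], start = start, end = start + width)
  })
}

# uniform non-overlapping placement of segments of given lengths on [0, L):
# shuffle order, draw gaps uniformly over the free space
place_nonoverlap <- function(lengths, L, offset = 0) {
  g <- length(lengths)
  if (g == 0) return(numeric(0))
  free <- L - sum(lengths)
  if (free < 0) stop("cannot place segments without overlap: total length ",
                     sum(lengths), " exceeds available span ", L)
  ord <- sample.int(g)
  gaps <- sort(stats::runif(g, 0, free))
  starts_in_order <- floor(gaps + cumsum(c(0, lengths[ord][-g])))
  starts <- numeric(g)
  starts[ord] <- starts_in_order
  starts + offset
}

#' Simulate a gene table with coordinated TADs
#'
#' Places genes non-overlapping within each planted TAD (Poisson counts;
#' coordinated TADs receive exactly `coord_genes` genes), draws log2
#' fold-changes from a null Normal centered at 0 except in coordinated TADs
#' where the planted direction shifts the mean by the effect size, and
#' draws adjusted p-values Uniform(0,1) under the null and Beta(shape, 1)
#' for coordinated genes. Fold-changes are stored on the linear scale.
#'
#' @param plan a [genome_plan].
#' @return data.frame of class `gene_table` with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `baseline`, `fc`, `padj`.
#' @export
simulate_genes <- function(plan) {
  bs <- plan$binning$bin_size
  with_seed(plan$seed + 31L, {
    rows <- list()
    gid <- 0L
    for (chrom in plan$binning$chrom) {
      td <- plan$tads[[chrom]]
      chrom_len <- plan$binning$length[match(chrom, plan$binning$chrom)]
      for (k in seq_len(nrow(td))) {
        coord <- plan$coord_tads
        cc <- if (!is.null(coord))
          coord[coord$chrom == chrom & coord$tad_index == k, , drop = FALSE]
        else NULL
        is_coord <- !is.null(cc) && nrow(cc) == 1
        ng <- if (is_coord) plan$coord_genes else stats::rpois(1, plan$genes_per_tad)
        if (ng == 0) next
        span_start <- td$start_bin[k] * bs
        span_end <- min(td$end_bin[k] * bs, chrom_len)
        len <- round(stats::runif(ng, plan$gene_length[1], plan$gene_length[2]))
        starts <- place_nonoverlap(len, span_end - span_start, span_start)
        mu <- if (is_coord) cc$direction * cc$effect else 0
        l2fc <- stats::rnorm(ng, mu, plan$fc_log2_sd)
        padj <- if (is_coord) stats::rbeta(ng, plan$padj_alt_shape, 1)
                else stats::runif(ng)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("g%05d", gid + seq_len(ng)),
          chrom = chrom, start = starts, end = starts + len,
          strand = sample(c("+", "-"), ng, replace = TRUE),
          baseline = stats::rlnorm(ng, 3, 1),
          fc = 2^l2fc, padj = padj)
        gid <- gid + ng
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(match(out$chrom, plan$binning$chrom), out$start), ]
    rownames(out) <- NULL
    class(out) <- c("gene_table", "data.frame")
    out
  })
}

#' Ground truth of a plan
#'
#' Everything planted by the plan, for checking recovery: per-bin
#' compartment labels per condition and the flipped set, TAD border
#' positions with insulation depths (the smaller of the two flanking TAD
#' depths), coordinated-TAD directions, variant GC couplings and the band
#' table.
#'
#' @param plan a [genome_plan].
#' @return list of class `plan_truth`.
#' @export
plan_truth <- function(plan) {
  b <- bins_df(plan$binning)
  b$comp_wt <- unlist(plan$comp_wt, use.names = FALSE)
  b$comp_kd <- unlist(plan$comp_kd, use.names = FALSE)
  b$flipped <- unlist(plan$flip, use.names = FALSE)
  borders <- do.call(rbind, lapply(plan$binning$chrom, function(chrom) {
    td <- plan$tads[[chrom]]
    if (nrow(td) < 2) return(NULL)
    data.frame(chrom = chrom,
               bin = td$start_bin[-1],
               bp = td$start_bin[-1] * plan$binning$bin_size,
               depth = pmin(td$tau[-nrow(td)], td$tau[-1]))
  }))
  structure(list(bins = b, borders = borders, coord_tads = plan$coord_tads,
                 variant_couplings = plan$couplings, bands = plan$bands,
                 local_gain = plan$local_gain, seed = plan$seed),
            class = "plan_truth")
}

#' Simulate a complete two-condition study
#'
#' Convenience wrapper: Hi-C matrices for both conditions, all signal
#' tracks, ATAC peaks, the gene table and the ground truth.
#'
#' @param plan a [genome_plan].
#' @return list with `wt`, `kd` ([contact_matrix]), `tracks`, `peaks_wt`,
#'   `peaks_kd`, `genes`, `truth`, `plan`.
#' @export
simulate_study <- function(plan) {
  list(wt = simulate_hic(plan, "WT"),
       kd = simulate_hic(plan, "KD"),
       tracks = simulate_tracks(plan),
       peaks_wt = simulate_atac_peaks(plan, "WT"),
       peaks_kd = simulate_atac_peaks(plan, "KD"),
       genes = simulate_genes(plan),
       truth = plan_truth(plan),
       plan = plan)
}

#' Read/write gene tables as BED6+3
#'
#' Columns: chrom, start, end, name, score (0), strand, baseFC, adjP,
#' baselineExpr.
#'
#' @param genes a `gene_table` data.frame.
#' @param path file path.
#' @return `write_genes`: the path, invisibly; `read_genes`: a `gene_table`.
#' @export
write_genes <- function(genes, path) {
  df <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                   name = genes$gene_id, score = 0, strand = genes$strand,
                   baseFC = format(genes$fc, digits = 15, trim = TRUE),
                   adjP = format(genes$padj, digits = 15, trim = TRUE),
                   baselineExpr = format(genes$baseline, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genes
#' @export
read_genes <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score",
                                        "strand", "baseFC", "adjP", "baselineExpr"))
  out <- data.frame(gene_id = df$name, chrom = df$chrom, start = df$start,
                    end = df$end, strand = df$strand, baseline = df$baselineExpr,
                    fc = df$baseFC, padj = df$adjP)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Segmentation object from the planted TAD plan
#'
#' Builds a `tad_segmentation` directly from a plan's planted TADs, so
#' downstream operations (gene assignment, permutation test, aggregation)
#' can be exercised against ground truth independently of the caller.
#'
#' @param plan a [genome_plan].
#' @return a `tad_segmentation` (border strengths unset).
#' @export
plan_segmentation <- function(plan) {
  bs <- plan$binning$bin_size
  tads <- do.call(rbind, lapply(plan$binning$chrom, function(ch) {
    td <- plan$tads[[ch]]
    data.frame(chrom = ch, start_bin = td$start_bin, end_bin = td$end_bin,
               start_bp = td$start_bin * bs,
               end_bp = pmin(td$end_bin * bs,
                             plan$binning$length[match(ch, plan$binning$chrom)]))
  }))
  borders <- do.call(rbind, lapply(plan$binning$chrom, function(ch) {
    td <- plan$tads[[ch]]
    if (nrow(td) < 2) return(NULL)
    data.frame(chrom = ch, bin = td$start_bin[-1],
               bp = td$start_bin[-1] * bs, strength = NA_real_)
  }))
  structure(list(tads = tads,
                 borders = if (is.null(borders))
                   data.frame(chrom = character(), bin = integer(),
                              bp = numeric(), strength = numeric())
                 else borders,
                 binning = plan$binning, condition = "planted",
                 objective = NULL, min_size = 2L, max_tads = NULL,
                 band = NULL, density = NA_real_),
            class = "tad_segmentation")
}
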
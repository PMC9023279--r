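# Shared simulation fixtures. Expensive objects are cached per test run so
# unit and acceptance tests can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default study genome (2 x 20 Mb, 100-kb bins, eps 0.3)
default_plan <- function(seed = 2) genome_plan(seed = seed)

# TAD recovery: one 22.5-Mb chromosome at 50-kb bins, 9 TADs of 2.5 Mb
# (8 planted borders), uniform insulation tau = 1
tad_recovery_plan <- function(seed = 6)
  genome_plan(chrom_lengths = c(chr1 = 22.5e6), bin_size = 50e3,
              tad_bp = 2.5e6, tau = 1.0, seed = seed)

# mixed-depth borders: insulation ladder along one 40-Mb chromosome
tad_ladder_plan <- function(seed = 6)
  genome_plan(chrom_lengths = c(chr1 = 40e6), bin_size = 50e3,
              tad_bp = 2.5e6, tau = seq(0.4, 2.0, length.out = 16),
              seed = seed)

# long-range gain: a 60-Mb chromosome so distances beyond 30 Mb exist
decay_plan <- function(seed = 5)
  genome_plan(chrom_lengths = c(chr1 = 60e6), bin_size = 500e3,
              tad_bp = 2.5e6, gamma = 0.4, delta = 0.3, seed = seed)

# KD local gain inside the low-GC (H1.2-rich) bands, so the D-score couples
# positively to H1.2 and negatively to H1X
coupled_plan <- function(seed = 8, factor = 1.4) {
  base <- genome_plan(seed = seed)
  low_gc <- base$bands[base$bands$gc_mean < stats::median(base$bands$gc_mean),
                       c("chrom", "start", "end")]
  genome_plan(seed = seed, gamma = 0, delta = 0,
              local_gain = list(regions = low_gc, factor = factor))
}

# genes with no planted coordination (null for the permutation test)
null_gene_plan <- function(seed) genome_plan(seed = seed, n_coord_up = 0,
                                             n_coord_down = 0)

# strong planted coordination: 8 TADs with >= 90% up-regulated genes
coord_plan <- function(seed = 13)
  genome_plan(seed = seed, n_coord_up = 8, n_coord_down = 0,
              coord_effect = 1.5)

balanced_pair <- function(plan) {
  list(wt = balance(normalize_depth(simulate_hic(plan, "WT"))),
       kd = balance(normalize_depth(simulate_hic(plan, "KD"))))
}

# tiny contact matrix from an explicit dense matrix
toy_cm <- function(M, bin_size = 1e5, chrom = "chrA", condition = "WT",
                   norm = "raw") {
  b <- genome_binning(stats::setNames(nrow(M) * bin_size, chrom), bin_size)
  contact_matrix(stats::setNames(list(M), chrom), b,
                 condition = condition, norm = norm)
}

pipeline_fixture <- function()
  cached("pipe_run",
         run_pipeline(pipeline_config(plan = genome_plan(seed = 3),
                                      outdir = tempfile("tadshift_pipe"),
                                      n_perm = 2000)))

# independent brute-force implementation of the segmentation objective, used
# as the exhaustive-search oracle: segment-mean Gaussian gain over the
# chromosome background, BIC penalty of 0.5*log(n_pairs) per border
oracle_objective <- function(M, starts, band = Inf) {
  n <- nrow(M)
  x <- M
  diag(x) <- NA
  x[abs(row(x) - col(x)) > band] <- NA
  vals <- x[upper.tri(x)]
  vals <- vals[!is.na(vals)]
  mu0 <- mean(vals); s20 <- stats::var(vals)
  if (!is.finite(s20) || s20 <= 0) s20 <- 1
  pen <- 0.5 * log(length(vals))
  ends <- c(starts[-1] - 1L, n)
  total <- 0
  for (k in seq_along(starts)) {
    sub <- x[starts[k]:ends[k], starts[k]:ends[k], drop = FALSE]
    v <- sub[upper.tri(sub)]
    v <- v[!is.na(v)]
    if (length(v))
      total <- total + length(v) * (mean(v) - mu0)^2 / (2 * s20)
  }
  total - (length(starts) - 1L) * pen
}

# all partitions of 1..n into segments >= min_size with at most k borders
all_partitions <- function(n, max_borders, min_size = 3L) {
  out <- list(1L)
  positions <- seq(min_size + 1L, n - min_size + 1L)
  for (k in seq_len(max_borders)) {
    if (length(positions) < k) break
    combs <- utils::combn(positions, k, simplify = FALSE)
    for (cc in combs) {
      segs <- diff(c(1L, cc, n + 1L))
      if (all(segs >= min_size)) out[[length(out) + 1L]] <- c(1L, cc)
    }
  }
  out
}


# hand-computed 12-gene toy covering every classify_de branch
toy_genes <- function() {
  data.frame(
    gene_id = sprintf("g%02d", 1:12), chrom = "chrA",
    start = seq(0, by = 2e4, length.out = 12),
    end = seq(0, by = 2e4, length.out = 12) + 1e4,
    strand = rep(c("+", "-"), 6),
    baseline = 10,
    fc =  c(1.5, 1.4, 2.0, 1.39, 0.5, 1 / 1.4, 0.72, 0.9, 1.0, 3.0, 0.2, 1.1),
    padj = c(0.01, 0.05, 0.2, 0.01, 0.01, 0.05, 0.01, 0.01, 0.5, 0.049, 0.051, 0.5))
}

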
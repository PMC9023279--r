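#' Genome binning
#'
#' A fixed-width binning of a genome: ordered chromosomes with lengths in bp
#' and a common bin size. Bins are 0-based half-open; the number of bins per
#' chromosome is `ceiling(length / bin_size)` (the last bin may be partial)
#' and global bin indices are contiguous across chromosomes in order.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp, > 0.
#' @return an object of class `genome_binning`.
#' @export
genome_binning <- function(chrom_lengths, bin_size) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (length(bin_size) != 1L || bin_size <= 0) stop("bin_size must be a single positive number")
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  structure(
    list(
      chrom  = names(chrom_lengths),
      length = unname(chrom_lengths),
      bin_size = bin_size,
      n_bins = n_bins,
      offset = c(0L, cumsum(n_bins)[-length(n_bins)])
    ),
    class = "genome_binning"
  )
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("genome_binning: %d chromosome(s), bin size %s bp, %d bins total\n",
              length(x$chrom), format(x$bin_size, big.mark = ","), sum(x$n_bins)))
  invisible(x)
}

n_bins_total <- function(binning) sum(binning$n_bins)

chrom_bins <- function(binning, chrom) {
  i <- match(chrom, binning$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  binning$n_bins[i]
}

#' Per-bin coordinate table
#'
#' @param binning a [genome_binning].
#' @return data.frame with one row per bin: `chrom`, `start`, `end`
#'   (0-based half-open, end clipped to the chromosome length) and the
#'   global 0-based `bin` index.
#' @export
bins_df <- function(binning) {
  out <- do.call(rbind, lapply(seq_along(binning$chrom), function(i) {
    n <- binning$n_bins[i]
    start <- (seq_len(n) - 1L) * binning$bin_size
    data.frame(
      chrom = binning$chrom[i],
      start = start,
      end = pmin(start + binning$bin_size, binning$length[i]),
      bin = binning$offset[i] + seq_len(n) - 1L
    )
  }))
  rownames(out) <- NULL
  out
}

same_binning <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$bin_size, b$bin_size) &&
    identical(a$n_bins, b$n_bins) && isTRUE(all.equal(a$length, b$length))
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
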
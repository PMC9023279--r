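#' Contact matrix container
#'
#' Per-chromosome symmetric intra-chromosomal contact matrices tied to a
#' [genome_binning]. Only cis contacts are represented; each chromosome owns
#' a square symmetric matrix of non-negative finite values (raw counts or
#' normalized weights). `NA` entries mark masked cells (e.g. zero-coverage
#' rows after balancing, or distances with zero expected value after
#' observed/expected transformation).
#'
#' @param mats named list of symmetric matrices, one per chromosome of
#'   `binning`, in the same order.
#' @param binning a [genome_binning].
#' @param condition condition label (e.g. `"WT"`, `"KD"`).
#' @param norm normalization state: one of `"raw"`, `"depth"`, `"balanced"`,
#'   `"oe"`.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(mats, binning, condition = "WT", norm = "raw") {
  stopifnot(inherits(binning, "genome_binning"))
  norm <- match.arg(norm, c("raw", "depth", "balanced", "oe"))
  if (!identical(names(mats), binning$chrom))
    stop("matrix list names must match binning chromosomes")
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    n <- binning$n_bins[i]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("matrix dimension mismatch for ", binning$chrom[i])
    if (any(is.finite(m) & m < 0)) stop("negative contact values in ", binning$chrom[i])
    asym <- abs(m - t(m))
    if (any(!is.na(asym)) && max(asym, na.rm = TRUE) > 1e-9)
      stop("matrix for ", binning$chrom[i], " is not symmetric")
  }
  structure(list(mats = mats, binning = binning, condition = condition, norm = norm),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix [%s, %s]: %d chromosome(s) at %s bp bins\n",
              x$condition, x$norm, length(x$mats),
              format(x$binning$bin_size, big.mark = ",")))
  invisible(x)
}

offdiag_sum <- function(m) sum(m, na.rm = TRUE) - sum(diag(m), na.rm = TRUE)

#' Read a contact matrix from dense or COO text files
#'
#' Dense files are whitespace-separated square numeric tables; symmetry is
#' required to within 1e-9. COO files have three columns
#' `bin_i bin_j count` with 0-based chromosome-local bin indices; upper- (or
#' lower-) triangle entries are mirrored and missing entries are zero.
#'
#' @param paths character vector of file paths named by chromosome; must
#'   cover every chromosome of `binning`.
#' @param format `"dense"` or `"coo"`.
#' @param binning a [genome_binning].
#' @param condition condition label stored on the result.
#' @return a [contact_matrix] with `norm = "raw"`.
#' @export
read_contact_matrix <- function(paths, format = c("dense", "coo"), binning,
                                condition = "WT") {
  format <- match.arg(format)
  if (is.null(names(paths))) stop("paths must be named by chromosome")
  if (!all(binning$chrom %in% names(paths)))
    stop("paths missing for chromosomes: ",
         paste(setdiff(binning$chrom, names(paths)), collapse = ", "))
  mats <- lapply(seq_along(binning$chrom), function(i) {
    chrom <- binning$chrom[i]
    n <- binning$n_bins[i]
    if (format == "dense") {
      m <- as.matrix(utils::read.table(paths[[chrom]], header = FALSE))
      dimnames(m) <- NULL
      if (nrow(m) != n || ncol(m) != n)
        stop("dense matrix for ", chrom, " is not ", n, "x", n)
      if (max(abs(m - t(m))) > 1e-9) stop("asymmetric dense input for ", chrom)
      m
    } else {
      coo <- utils::read.table(paths[[chrom]], header = FALSE,
                               col.names = c("bin_i", "bin_j", "count"))
      if (any(coo$count < 0)) stop("negative count in COO input for ", chrom)
      if (any(coo$bin_i < 0 | coo$bin_j < 0 | coo$bin_i >= n | coo$bin_j >= n))
        stop("bin index out of range in COO input for ", chrom)
      m <- matrix(0, n, n)
      m[cbind(coo$bin_i + 1L, coo$bin_j + 1L)] <- coo$count
      m[cbind(coo$bin_j + 1L, coo$bin_i + 1L)] <- coo$count
      m
    }
  })
  names(mats) <- binning$chrom
  contact_matrix(mats, binning, condition = condition, norm = "raw")
}

#' Write a contact matrix as dense TSV or COO text
#'
#' One file per chromosome, named `<prefix>.<chrom>.tsv` (dense) or
#' `<prefix>.<chrom>.coo` (COO, upper triangle including the diagonal,
#' 0-based bins, zero entries omitted).
#'
#' @param m a [contact_matrix].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default the condition label.
#' @param format `"dense"` or `"coo"`.
#' @return invisibly, the paths written (named by chromosome).
#' @export
write_contact_matrix <- function(m, dir, prefix = m$condition,
                                 format = c("dense", "coo")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(m$binning$chrom), function(i) {
    chrom <- m$binning$chrom[i]
    mat <- m$mats[[i]]
    if (format == "dense") {
      path <- file.path(dir, sprintf("%s.%s.tsv", prefix, chrom))
      utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                         path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      path <- file.path(dir, sprintf("%s.%s.coo", prefix, chrom))
      idx <- which(upper.tri(mat, diag = TRUE) & mat != 0 & !is.na(mat), arr.ind = TRUE)
      coo <- data.frame(bin_i = idx[, 1L] - 1L, bin_j = idx[, 2L] - 1L,
                        count = mat[idx])
      coo <- coo[order(coo$bin_i, coo$bin_j), ]
      utils::write.table(coo, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    path
  }, character(1))
  names(paths) <- m$binning$chrom
  invisible(paths)
}

#' Equalize sequencing depth across conditions
#'
#' Rescales each chromosome by a single multiplicative factor so that its
#' off-diagonal sum equals `target_sum`, making matrices from libraries of
#' different depth directly comparable.
#'
#' @param m a [contact_matrix].
#' @param target_sum target off-diagonal sum per chromosome.
#' @return a depth-normalized [contact_matrix].
#' @export
normalize_depth <- function(m, target_sum = 1e6) {
  mats <- lapply(seq_along(m$mats), function(i) {
    s <- offdiag_sum(m$mats[[i]])
    if (s <= 0) stop("chromosome ", m$binning$chrom[i],
                     " has no off-diagonal contacts; cannot depth-normalize")
    m$mats[[i]] * (target_sum / s)
  })
  names(mats) <- m$binning$chrom
  contact_matrix(mats, m$binning, condition = m$condition, norm = "depth")
}

#' Iterative proportional fitting (ICE-style balancing)
#'
#' Removes multiplicative per-bin biases by iteratively dividing each
#' chromosome matrix by the outer product of its row-sum biases until the
#' coefficient of variation of unmasked row sums falls below `tol`. Rows with
#' zero off-diagonal coverage are masked (`NA`) and excluded. The total
#' off-diagonal mass of each chromosome is preserved, so depth equalization
#' performed beforehand survives balancing.
#'
#' @param m a depth-normalized [contact_matrix].
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the CV of unmasked row sums.
#' @return a balanced [contact_matrix]; chromosomes that fail to converge
#'   are reported with a warning.
#' @export
balance <- function(m, max_iter = 200, tol = 1e-5) {
  mats <- lapply(seq_along(m$mats), function(i) {
    mat <- m$mats[[i]]
    n <- nrow(mat)
    diag_vals <- diag(mat)
    diag(mat) <- 0
    keep <- rowSums(mat, na.rm = TRUE) > 0
    if (sum(keep) < 2) {
      mat[] <- NA_real_
      return(mat)
    }
    w <- mat[keep, keep, drop = FALSE]
    total <- sum(w)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      rs <- rowSums(w)
      if (stats::sd(rs) / mean(rs) < tol) { converged <- TRUE; break }
      b <- rs / mean(rs)
      w <- w / outer(sqrt(b), sqrt(b))
    }
    if (!converged)
      warning("balancing did not converge for ", m$binning$chrom[i],
              " after ", max_iter, " iterations")
    w <- w * (total / sum(w))
    out <- matrix(NA_real_, n, n)
    out[keep, keep] <- w
    # diagonal carried through unbalanced but rescaled rows masked; it is
    # excluded from all downstream statistics anyway
    diag(out) <- ifelse(keep, diag_vals, NA_real_)
    out
  })
  names(mats) <- m$binning$chrom
  contact_matrix(mats, m$binning, condition = m$condition, norm = "balanced")
}

#' Mean contact value as a function of genomic distance
#'
#' Pools all intra-chromosomal bin pairs at each separation d >= 1 (in bins)
#' across chromosomes and returns the mean value per distance. The diagonal
#' is excluded. Masked (`NA`) entries are dropped from both numerator and
#' denominator.
#'
#' @param m a [contact_matrix].
#' @return data.frame of class `decay_curve`: `distance` (bins),
#'   `distance_bp`, `mean`, plus the condition label as an attribute.
#' @export
expected_by_distance <- function(m) {
  max_d <- max(m$binning$n_bins) - 1L
  sums <- numeric(max_d)
  cnts <- numeric(max_d)
  for (mat in m$mats) {
    n <- nrow(mat)
    if (n < 2) next
    d <- row(mat) - col(mat)     # use lower triangle: d >= 1
    sel <- d >= 1
    dd <- d[sel]
    vv <- mat[sel]
    ok <- !is.na(vv)
    sums_c <- rowsum(vv[ok], dd[ok])
    cnts_c <- rowsum(rep(1, sum(ok)), dd[ok])
    at <- as.integer(rownames(sums_c))
    sums[at] <- sums[at] + sums_c[, 1]
    cnts[at] <- cnts[at] + cnts_c[, 1]
  }
  out <- data.frame(distance = seq_len(max_d),
                    distance_bp = seq_len(max_d) * m$binning$bin_size,
                    mean = ifelse(cnts > 0, sums / cnts, NA_real_))
  out <- out[cnts > 0, ]
  rownames(out) <- NULL
  attr(out, "condition") <- m$condition
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Observed/expected transformation (decay correction)
#'
#' Divides every entry by the genome-wide mean contact value at its
#' separation. Distances with zero expected value, and the diagonal, are
#' masked (`NA`).
#'
#' @param m a normalized [contact_matrix].
#' @return a [contact_matrix] with `norm = "oe"`.
#' @export
observed_over_expected <- function(m) {
  curve <- expected_by_distance(m)
  exp_at <- rep(NA_real_, max(m$binning$n_bins))
  exp_at[curve$distance] <- curve$mean
  exp_at[!is.na(exp_at) & exp_at == 0] <- NA_real_
  mats <- lapply(m$mats, function(mat) {
    n <- nrow(mat)
    d <- abs(row(mat) - col(mat))
    e <- matrix(NA_real_, n, n)
    sel <- d >= 1
    e[sel] <- exp_at[d[sel]]
    mat / e
  })
  names(mats) <- m$binning$chrom
  contact_matrix(mats, m$binning, condition = m$condition, norm = "oe")
}

#' Compare distance-decay curves between conditions
#'
#' Computes the per-distance log2 ratio of two decay curves on identical
#' grids, and its mean below and above a genomic-distance split (default
#' 30 Mb, the scale separating the short/medium-range regime from
#' long-range contacts).
#'
#' @param wt,kd `decay_curve` objects on identical distance grids.
#' @param split_bp distance (bp) separating the two regimes.
#' @return list with `per_distance` (data.frame of distance and log2 ratio),
#'   `mean_log2_below`, `mean_log2_above`.
#' @export
decay_contrast <- function(wt, kd, split_bp = 30e6) {
  if (!isTRUE(all.equal(wt$distance, kd$distance)) ||
      !isTRUE(all.equal(wt$distance_bp, kd$distance_bp)))
    stop("decay curves are on different distance grids")
  lr <- ifelse(wt$mean > 0 & kd$mean > 0, log2(kd$mean / wt$mean), NA_real_)
  below <- wt$distance_bp < split_bp
  list(
    per_distance = data.frame(distance = wt$distance,
                              distance_bp = wt$distance_bp, log2_ratio = lr),
    mean_log2_below = if (any(below & !is.na(lr))) mean(lr[below], na.rm = TRUE) else NA_real_,
    mean_log2_above = if (any(!below & !is.na(lr))) mean(lr[!below], na.rm = TRUE) else NA_real_
  )
}

#' Coarsen a contact matrix by an integer factor
#'
#' Sums counts over `factor` x `factor` blocks; a trailing partial block is
#' allowed. Total mass (diagonal included) is conserved exactly.
#'
#' @param m a [contact_matrix].
#' @param factor positive integer.
#' @return a [contact_matrix] at `bin_size * factor`.
#' @export
rebin <- function(m, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(m)
  lengths <- stats::setNames(m$binning$length, m$binning$chrom)
  new_binning <- genome_binning(lengths, m$binning$bin_size * factor)
  mats <- lapply(seq_along(m$mats), function(i) {
    mat <- m$mats[[i]]
    grp <- (seq_len(nrow(mat)) - 1L) %/% factor + 1L
    res <- t(rowsum(t(rowsum(mat, grp)), grp))
    dimnames(res) <- NULL
    (res + t(res)) / 2     # enforce exact symmetry of the float block sums
  })
  names(mats) <- m$binning$chrom
  contact_matrix(mats, new_binning, condition = m$condition, norm = m$norm)
}
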
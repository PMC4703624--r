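#' Depth bin specification
#'
#' Ordered bin edges for grouping SNPs by their mean sequencing depth.
#' Bins are left-open/right-closed `(lo, hi]`, except the first bin which
#' also includes its lower edge (so depth 0 falls in the first bin).
#'
#' @param edges strictly increasing numeric vector of bin edges
#'   (default `c(0, 10, 20, 30, 40, 60)`).
#' @param labels optional labels, one per bin; default `"lo-hi"`.
#' @return An object of class `depth_bin_spec`.
#' @export
depth_bin_spec <- function(edges = c(0, 10, 20, 30, 40, 60), labels = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L) stop("need at least two bin edges")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1L
  if (is.null(labels))
    labels <- paste0(edges[-length(edges)], "-", edges[-1L])
  if (length(labels) != nb) stop("need one label per bin (", nb, ")")
  structure(list(edges = edges, labels = as.character(labels)),
            class = "depth_bin_spec")
}

#' Filter SNPs on mean depth and mean allele frequency
#'
#' Drops SNPs whose mean read depth across families exceeds
#' `max_mean_depth` (suspected repetitive/plastid loci), then SNPs whose
#' mean non-missing allele frequency falls outside
#' `[min_freq, max_freq]` (near-monomorphic loci). Bounds are inclusive:
#' a SNP at exactly 0.02 or 0.98 is retained. Mean depth is taken over all
#' families, counting zero-depth (missing) cells.
#'
#' @param x a [pool_freq()] object.
#' @param max_mean_depth maximum mean read depth (default 60); set `Inf`
#'   to skip (required when `x` has no depth matrix).
#' @param min_freq,max_freq inclusive bounds on the mean frequency
#'   (defaults 0.02 and 0.98).
#' @return The filtered `pool_freq`, with attribute `"report"`: a list with
#'   `n_in`, `n_removed_depth`, `n_removed_freq`, `n_out`.
#' @export
filter_snps <- function(x, max_mean_depth = 60, min_freq = 0.02,
                        max_freq = 0.98) {
  x <- as_pool_freq(x)
  n_in <- nrow(x$values)
  keep <- rep(TRUE, n_in)
  n_depth <- 0L
  if (is.finite(max_mean_depth)) {
    md <- snp_mean_depth(x)
    bad <- md > max_mean_depth
    n_depth <- sum(bad)
    keep <- keep & !bad
  }
  mf <- rowMeans(x$values, na.rm = TRUE)
  bad_f <- keep & (is.nan(mf) | mf < min_freq | mf > max_freq)
  n_freq <- sum(bad_f)
  keep <- keep & !bad_f
  if (!any(keep))
    stop("all ", n_in, " SNPs removed by depth/frequency filters")
  out <- subset_pool_freq(x, snps = which(keep))
  attr(out, "report") <- list(n_in = n_in, n_removed_depth = n_depth,
                              n_removed_freq = as.integer(n_freq),
                              n_out = sum(keep))
  out
}

#' Assign SNPs to sequencing-depth bins
#'
#' Groups SNPs by mean read depth into the bins of a [depth_bin_spec()].
#' SNPs with mean depth above the last edge are excluded (mirroring the
#' high-depth discard) and counted in a warning.
#'
#' @param x a [pool_freq()] object carrying read depths.
#' @param bins a [depth_bin_spec()].
#' @return Named list mapping bin label to integer vector of SNP row
#'   indices; attribute `"n_above"` counts SNPs above the last edge.
#' @export
assign_depth_bins <- function(x, bins = depth_bin_spec()) {
  x <- as_pool_freq(x)
  if (!inherits(bins, "depth_bin_spec")) stop("'bins' must be a depth_bin_spec")
  out <- stats::setNames(vector("list", length(bins$labels)), bins$labels)
  for (i in seq_along(out)) out[[i]] <- integer(0)
  if (nrow(x$values) == 0L) {
    attr(out, "n_above") <- 0L
    return(out)
  }
  md <- snp_mean_depth(x)
  # (lo, hi] with the first bin closed on the left
  idx <- findInterval(md, bins$edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[md == bins$edges[1L]] <- 1L          # first bin includes its lower edge
  idx[idx == 0L] <- NA_integer_            # below the first edge
  above <- md > bins$edges[length(bins$edges)]
  if (any(above, na.rm = TRUE)) {
    warning(sum(above), " SNP(s) above the last depth edge (",
            bins$edges[length(bins$edges)], ") excluded from binning")
    idx[above] <- NA_integer_
  }
  idx[idx > length(bins$labels)] <- NA_integer_
  for (b in seq_along(bins$labels))
    out[[b]] <- which(!is.na(idx) & idx == b)
  attr(out, "n_above") <- sum(above, na.rm = TRUE)
  out
}

#' Filter families on genotype missing rate
#'
#' Drops families whose fraction of missing SNP calls exceeds
#' `max_missing_rate`.
#'
#' @param x a [pool_freq()] object.
#' @param max_missing_rate maximum tolerated missing fraction (default 0.5).
#' @return The filtered `pool_freq` with attribute `"report"`:
#'   `n_in`, `n_removed`, `n_out`, `removed_ids`.
#' @export
filter_families <- function(x, max_missing_rate = 0.5) {
  x <- as_pool_freq(x)
  n_in <- ncol(x$values)
  miss <- colMeans(is.na(x$values))
  keep <- miss <= max_missing_rate
  if (!any(keep))
    stop("all ", n_in, " families exceed missing rate ", max_missing_rate)
  out <- subset_pool_freq(x, families = which(keep))
  attr(out, "report") <- list(n_in = n_in, n_removed = sum(!keep),
                              n_out = sum(keep),
                              removed_ids = x$family_ids[!keep])
  out
}

#' Randomly subsample SNPs
#'
#' Draws `n` SNPs uniformly without replacement, e.g. to compare GRMs at
#' equal marker density across depth bins.
#'
#' @param x a [pool_freq()] object.
#' @param n number of SNPs to keep (1 <= n <= number of SNPs).
#' @param seed optional integer seed.
#' @return A `pool_freq` with `n` SNP rows (in original row order).
#' @export
subsample_snps <- function(x, n, seed = NULL) {
  x <- as_pool_freq(x)
  n_snps <- nrow(x$values)
  if (n < 1) stop("'n' must be at least 1")
  if (n > n_snps)
    stop("requested ", n, " SNPs but only ", n_snps, " available")
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(n_snps, n))
  subset_pool_freq(x, snps = keep)
}
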
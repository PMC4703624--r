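#' Pool allele-frequency matrix
#'
#' Container for GBS allele-frequency estimates of family-pool samples:
#' a SNP x family matrix of frequencies in \[0, 1\] with `NA` marking
#' missing calls, and an optional matching matrix of read depths.
#' For GBS data a depth of 0 and a missing frequency coincide: no reads,
#' no estimate.
#'
#' @param values numeric SNP x family matrix of allele frequencies in
#'   \[0, 1\]; `NA` for missing calls.
#' @param depths optional non-negative read-depth matrix of the same shape.
#' @param snp_ids,family_ids label vectors; default to the dimnames of
#'   `values`, or `snp_1..n` / `fam_1..m` when absent.
#' @return An object of class `pool_freq` with elements `values`, `depths`,
#'   `snp_ids`, `family_ids`.
#' @examples
#' pf <- pool_freq(matrix(c(0.25, 0.5, NA, 0.75), 2, 2))
#' dim(pf)
#' @export
pool_freq <- function(values, depths = NULL, snp_ids = NULL, family_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(snp_ids)) {
    snp_ids <- rownames(values)
    if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(nrow(values)))
  }
  if (is.null(family_ids)) {
    family_ids <- colnames(values)
    if (is.null(family_ids)) family_ids <- paste0("fam_", seq_len(ncol(values)))
  }
  snp_ids <- as.character(snp_ids)
  family_ids <- as.character(family_ids)
  if (length(snp_ids) != nrow(values))
    stop("length of 'snp_ids' (", length(snp_ids), ") does not match ",
         nrow(values), " SNP rows")
  if (length(family_ids) != ncol(values))
    stop("length of 'family_ids' (", length(family_ids), ") does not match ",
         ncol(values), " family columns")
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP id: ", snp_ids[duplicated(snp_ids)][1L])
  if (anyDuplicated(family_ids))
    stop("duplicate family id: ", family_ids[duplicated(family_ids)][1L])
  if (length(values) && !all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1)
      stop("allele frequencies must lie in [0, 1]; found range [",
           rng[1L], ", ", rng[2L], "]")
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    storage.mode(depths) <- "double"
    if (!identical(dim(depths), dim(values)))
      stop("'depths' must have the same shape as 'values'")
    if (length(depths) && min(depths, na.rm = TRUE) < 0)
      stop("read depths must be non-negative")
    dimnames(depths) <- list(snp_ids, family_ids)
  }
  dimnames(values) <- list(snp_ids, family_ids)
  structure(list(values = values, depths = depths,
                 snp_ids = snp_ids, family_ids = family_ids),
            class = "pool_freq")
}

#' @export
dim.pool_freq <- function(x) dim(x$values)

#' @export
print.pool_freq <- function(x, ...) {
  cat("pool_freq: ", nrow(x$values), " SNPs x ", ncol(x$values),
      " families\n", sep = "")
  nmiss <- sum(is.na(x$values))
  cat("  missing calls: ", nmiss, " (",
      round(100 * nmiss / max(1L, length(x$values)), 2), "%)\n", sep = "")
  if (!is.null(x$depths))
    cat("  mean read depth: ", round(mean(x$depths), 2), "\n", sep = "")
  invisible(x)
}

#' Coerce to a pool_freq object
#'
#' @param x a `pool_freq` object or a numeric matrix of frequencies.
#' @param ... passed on to [pool_freq()] for matrix input.
#' @return A `pool_freq` object.
#' @export
as_pool_freq <- function(x, ...) {
  if (inherits(x, "pool_freq")) return(x)
  pool_freq(x, ...)
}

## internal: subset SNP rows (and optionally families) preserving structure
subset_pool_freq <- function(x, snps = NULL, families = NULL) {
  v <- x$values
  d <- x$depths
  if (!is.null(snps)) {
    v <- v[snps, , drop = FALSE]
    if (!is.null(d)) d <- d[snps, , drop = FALSE]
  }
  if (!is.null(families)) {
    v <- v[, families, drop = FALSE]
    if (!is.null(d)) d <- d[, families, drop = FALSE]
  }
  pool_freq(v, depths = d)
}

## internal: mean depth per SNP over ALL families (zero-depth cells count;
## depth 0 is a real sequencing outcome of the SNP)
snp_mean_depth <- function(x) {
  if (is.null(x$depths))
    stop("pool_freq object carries no read-depth matrix")
  rowMeans(x$depths)
}
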
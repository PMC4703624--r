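#' Center a frequency matrix by SNP means and impute missing cells
#'
#' Subtracts each SNP's mean allele frequency (computed over non-missing
#' families) from its row, and sets cells that were missing to exactly 0,
#' i.e. mean imputation in the centered matrix.
#'
#' @param x a [pool_freq()] object or frequency matrix (`NA` = missing).
#' @return An object of class `centered_freqs`: list with `M` (centered
#'   SNP x family matrix) and `snp_means`.
#' @export
center_and_impute <- function(x) {
  x <- as_pool_freq(x)
  v <- x$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0L))
    stop("SNP(s) with all families missing: ",
         paste(utils::head(x$snp_ids[n_obs == 0L], 5L), collapse = ", "))
  means <- rowMeans(v, na.rm = TRUE)
  M <- v - means
  M[is.na(M)] <- 0
  structure(list(M = M, snp_means = stats::setNames(means, x$snp_ids)),
            class = "centered_freqs")
}

#' GRM scaling constant
#'
#' The scaling constant `K = 0.25 * sum(p_i * (1 - p_i))` over SNP mean
#' frequencies `p_i`: the sum of expected per-SNP variances of F2
#' family-pool frequencies under independent founder copies (no
#' inbreeding).
#'
#' @param snp_means per-SNP mean allele frequencies in \[0, 1\].
#' @return The scalar `K` (> 0).
#' @export
grm_scaling_constant <- function(snp_means) {
  snp_means <- as.numeric(snp_means)
  if (length(snp_means) == 0L) stop("no SNPs: scaling constant undefined")
  if (min(snp_means) < 0 || max(snp_means) > 1)
    stop("SNP mean frequencies must lie in [0, 1]")
  K <- 0.25 * sum(snp_means * (1 - snp_means))
  if (K <= 0)
    stop("scaling constant K = 0 (all SNPs monomorphic); GRM undefined")
  K
}

#' Pool-level genomic relationship matrix
#'
#' VanRaden method-1 GRM adapted to family pools: with `M` the
#' SNP-mean-centered, mean-imputed frequency matrix,
#' `G = M'M / K` where `K = 0.25 * sum(p_i (1 - p_i))`. With
#' `missing_correction = TRUE` each element is instead scaled by a pairwise
#' constant `K_jk` summing only over SNPs observed in both families, so
#' relationships between poorly genotyped families are not shrunk by the
#' zero-imputed cells.
#'
#' @param x a [pool_freq()] object or frequency matrix.
#' @param missing_correction apply the pairwise missing-rate correction
#'   (default `FALSE`; recommended when the matrix has missing calls).
#' @return An object of class `pool_grm`: list with `G` (family x family),
#'   `K`, `mean_diagonal`, `mean_offdiagonal`, `n_snps`,
#'   `missing_correction`.
#' @export
compute_grm <- function(x, missing_correction = FALSE) {
  x <- as_pool_freq(x)
  cm <- center_and_impute(x)
  K <- grm_scaling_constant(cm$snp_means)
  num <- crossprod(cm$M)
  if (missing_correction) {
    obs <- (!is.na(x$values)) * 1
    w <- 0.25 * cm$snp_means * (1 - cm$snp_means)
    Kpair <- crossprod(obs * sqrt(w))          # K_jk over mutually observed SNPs
    if (any(Kpair <= 0)) {
      bad <- which(Kpair <= 0, arr.ind = TRUE)[1L, ]
      stop("pairwise scaling constant is zero for families '",
           x$family_ids[bad[1L]], "' and '", x$family_ids[bad[2L]],
           "'; no informative SNPs observed in both")
    }
    G <- num / Kpair
  } else {
    G <- num / K
  }
  d <- diag(G)
  structure(list(G = G, K = K, mean_diagonal = mean(d),
                 mean_offdiagonal = mean(G[row(G) != col(G)]),
                 n_snps = nrow(x$values),
                 missing_correction = missing_correction),
            class = "pool_grm")
}

#' @export
print.pool_grm <- function(x, ...) {
  cat("pool_grm: ", nrow(x$G), " families from ", x$n_snps, " SNPs\n",
      "  K = ", signif(x$K, 6), ", mean diagonal = ",
      signif(x$mean_diagonal, 4), ", mean off-diagonal = ",
      signif(x$mean_offdiagonal, 4),
      if (x$missing_correction) ", missing-rate corrected", "\n", sep = "")
  invisible(x)
}

#' Invert a (near-singular) GRM by eigenvalue repair
#'
#' A centered GRM has one (near-)zero eigenvalue. The smallest eigenvalue
#' is raised to `repair_factor` times the second-smallest ("a value just
#' below" it), and the inverse is assembled from the repaired spectrum:
#' `G_inv = E diag(1/lambda) E'`.
#'
#' @param G a `pool_grm` or a symmetric numeric matrix.
#' @param repair_factor fraction of the second-smallest eigenvalue given to
#'   the smallest (default 0.99; must be in (0, 1\]).
#' @return An object of class `repaired_inverse`: list with `G_inv`,
#'   `G_repaired` (the matrix actually inverted), `eigenvalues` (original),
#'   `eigenvalues_repaired`, `repair_factor`.
#' @export
invert_grm <- function(G, repair_factor = 0.99) {
  if (inherits(G, "pool_grm")) G <- G$G
  G <- as.matrix(G)
  if (nrow(G) != ncol(G) || max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("'G' must be a symmetric square matrix")
  if (repair_factor <= 0 || repair_factor > 1)
    stop("'repair_factor' must lie in (0, 1]")
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- ee$values                      # decreasing order
  n <- length(ev)
  if (n < 2L) stop("need at least a 2 x 2 matrix")
  if (ev[n - 1L] <= 0)
    stop("second-smallest eigenvalue is not positive (", ev[n - 1L],
         "); matrix not repairable by the smallest-eigenvalue rule")
  ev_rep <- ev
  ev_rep[n] <- repair_factor * ev[n - 1L]
  G_inv <- ee$vectors %*% (t(ee$vectors) / ev_rep)
  G_inv <- (G_inv + t(G_inv)) / 2
  G_rep <- ee$vectors %*% (t(ee$vectors) * ev_rep)
  G_rep <- (G_rep + t(G_rep)) / 2
  dimnames(G_inv) <- dimnames(G)
  dimnames(G_rep) <- dimnames(G)
  structure(list(G_inv = G_inv, G_repaired = G_rep, eigenvalues = ev,
                 eigenvalues_repaired = ev_rep,
                 repair_factor = repair_factor),
            class = "repaired_inverse")
}
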
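#' Depth-binned heritability pipeline for empirical-style data
#'
#' Mirrors the full analysis applied to field data: SNP filtering (mean
#' depth and mean frequency), family filtering on missing rate, grouping
#' of SNPs into sequencing-depth bins, one GRM per bin (missing-rate
#' corrected when the data carry missing calls), and per-bin REML fits of
#' the model `y = trial + genomic + family + pop + e` with the three
#' heritability estimators. The trial block enters as a fixed factor when
#' a `trial` column is present; the iid family term is included only when
#' at least one family has two or more replicates (it is confounded with
#' the residual otherwise, and dropped with a message); the
#' parent-population term requires `pop1`/`pop2` columns.
#'
#' @param freqs a [pool_freq()] object, or path of a frequency TSV.
#' @param depths optional depth matrix or TSV path (required for depth
#'   filtering/binning when `freqs` carries no depths).
#' @param phenotypes phenotype data frame or TSV path with columns
#'   `family`, `rep`, `value` and optionally `trial`, `pop1`, `pop2`.
#' @param bins a [depth_bin_spec()].
#' @param max_mean_depth,min_freq,max_freq SNP filter settings, see
#'   [filter_snps()].
#' @param max_missing_rate family filter setting, see [filter_families()].
#' @param subsample_sizes optional vector of SNP counts: each bin is also
#'   analysed on random subsamples of these sizes (sizes exceeding a bin
#'   are skipped).
#' @param ww_diag diagonal of `WW'` for the parent-population term
#'   (default 2).
#' @param min_bin_snps bins with fewer SNPs trigger a warning (default 100).
#' @param seed seed for SNP subsampling.
#' @param control a [reml_control()].
#' @return A data frame with one row per (depth bin, subsample size):
#'   bin label, `n_snps`, `mean_diag`, the variance components, and
#'   `h2_G`, `h2_G_PP`, `H2` with standard errors.
#' @export
run_empirical_pipeline <- function(freqs, depths = NULL, phenotypes,
                                   bins = depth_bin_spec(),
                                   max_mean_depth = 60, min_freq = 0.02,
                                   max_freq = 0.98, max_missing_rate = 0.5,
                                   subsample_sizes = NULL, ww_diag = 2,
                                   min_bin_snps = 100L, seed = 1L,
                                   control = reml_control()) {
  if (is.character(freqs))
    freqs <- read_frequency_matrix(freqs,
                                   depth_path = if (is.character(depths)) depths)
  else if (!is.null(depths) && is.null(freqs$depths))
    freqs <- pool_freq(as_pool_freq(freqs)$values, depths = depths)
  freqs <- as_pool_freq(freqs)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.null(freqs$depths))
    stop("depth matrix required for the depth-binned pipeline")

  freqs <- filter_snps(freqs, max_mean_depth = max_mean_depth,
                       min_freq = min_freq, max_freq = max_freq)
  freqs <- filter_families(freqs, max_missing_rate = max_missing_rate)

  fam_geno <- freqs$family_ids
  fam_pheno <- unique(phenotypes$family)
  only_geno <- setdiff(fam_geno, fam_pheno)
  only_pheno <- setdiff(fam_pheno, fam_geno)
  if (length(only_pheno))
    stop("families in phenotypes but not genotypes: ",
         paste(utils::head(only_pheno, 5L), collapse = ", "))
  if (length(only_geno))
    freqs <- subset_pool_freq(freqs, families = match(fam_pheno, fam_geno))
  phenotypes <- phenotypes[order(match(phenotypes$family, freqs$family_ids),
                                 phenotypes$rep), ]

  bin_map <- assign_depth_bins(freqs, bins)
  sizes <- c(NA_integer_, subsample_sizes)     # NA = all SNPs in the bin
  out <- list()
  for (b in names(bin_map)) {
    idx <- bin_map[[b]]
    if (length(idx) == 0L) next
    if (length(idx) < min_bin_snps)
      warning("depth bin ", b, " has only ", length(idx), " SNPs")
    for (s in sizes) {
      sub <- subset_pool_freq(freqs, snps = idx)
      if (!is.na(s)) {
        if (s > length(idx)) next
        sub <- subsample_snps(sub, s, seed = seed)
      }
      has_missing <- anyNA(sub$values)
      grm <- compute_grm(sub, missing_correction = has_missing)
      fit <- fit_pipeline_model(phenotypes, freqs$family_ids, grm$G,
                                control = control)
      h <- heritabilities(fit, mean_diag = grm$mean_diagonal,
                          ww_diag = ww_diag)
      out[[length(out) + 1L]] <- data.frame(
        bin = b, n_snps = if (is.na(s)) length(idx) else s,
        subsampled = !is.na(s), mean_diag = grm$mean_diagonal,
        sigma2_g = fit$varcomp[["genomic"]],
        sigma2_f = if ("family" %in% names(fit$varcomp))
          fit$varcomp[["family"]] else NA_real_,
        sigma2_p = if ("pop" %in% names(fit$varcomp))
          fit$varcomp[["pop"]] else NA_real_,
        sigma2_e = fit$varcomp[["residual"]],
        h2_G = h$h2_G, h2_G_se = h$se[["h2_G"]],
        h2_G_PP = h$h2_G_PP, h2_G_PP_se = h$se[["h2_G_PP"]],
        H2 = h$H2, H2_se = h$se[["H2"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no depth bin contained any SNPs")
  do.call(rbind, out)
}

## Build design matrices for the empirical model and fit it (dense path).
fit_pipeline_model <- function(pheno, family_ids, G, control = reml_control()) {
  fam <- factor(pheno$family, levels = family_ids)
  Z <- stats::model.matrix(~ 0 + fam)
  X <- if ("trial" %in% names(pheno) && length(unique(pheno$trial)) > 1L) {
    stats::model.matrix(~ factor(trial), data = pheno)
  } else {
    matrix(1, nrow(pheno), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  random <- list(genomic = list(Z = Z, K = G))
  reps_per_family <- table(pheno$family)
  if (max(reps_per_family) >= 2L) {
    random$family <- list(Z = Z)
  } else {
    message("one replicate per family: iid family term dropped ",
            "(confounded with the residual)")
  }
  if (all(c("pop1", "pop2") %in% names(pheno))) {
    pops <- sort(unique(c(pheno$pop1, pheno$pop2)))
    W <- matrix(0, nrow(pheno), length(pops),
                dimnames = list(NULL, pops))
    for (j in seq_len(nrow(pheno))) {
      W[j, as.character(pheno$pop1[j])] <- W[j, as.character(pheno$pop1[j])] + 1
      W[j, as.character(pheno$pop2[j])] <- W[j, as.character(pheno$pop2[j])] + 1
    }
    random$pop <- list(Z = W)
  }
  reml_fit(pheno$value, X = X, random = random, control = control)
}
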
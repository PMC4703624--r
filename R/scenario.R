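#' Run one simulation scenario with Monte Carlo replication
#'
#' Repeats the full chain of a scenario `n_datasets` times: simulate a
#' dataset, build the GRM from the observed (sequencing-noised)
#' frequencies using all SNPs without missing-rate correction, fit the
#' REML model (genomic + residual with one replicate; genomic + iid family
#' + residual with two), and compute the heritability estimators using the
#' mean diagonal of each dataset's own GRM. Per-dataset seeds are derived
#' deterministically from the root seed, so scenarios are reproducible and
#' independent of evaluation order.
#'
#' Datasets whose REML fit fails to converge are excluded from the summary
#' and counted; more than 20\% failures abort the scenario.
#'
#' @param scenario a [sim_scenario()].
#' @param n_datasets number of simulated datasets (default 50).
#' @param seed root seed; defaults to `scenario$seed`.
#' @param control a [reml_control()] for the per-dataset fits.
#' @return An object of class `scenario_summary`: the scenario, per-dataset
#'   estimate table, `mean` and `mc_se` (sd/sqrt(n)) of each estimator,
#'   mean GRM diagonal, dataset seeds and failure count. With
#'   `n_datasets = 1` the Monte Carlo SE is reported as `NA`.
#' @export
run_scenario <- function(scenario, n_datasets = 50L, seed = scenario$seed,
                         control = reml_control()) {
  if (!inherits(scenario, "sim_scenario"))
    stop("'scenario' must be a sim_scenario object")
  if (n_datasets < 1) stop("'n_datasets' must be at least 1")
  set.seed(seed)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  two_rep <- scenario$n_replicates == 2L
  rows <- vector("list", n_datasets)
  n_fail <- 0L
  for (i in seq_len(n_datasets)) {
    res <- tryCatch({
      ds <- simulate_pool_dataset(scenario, seed = dataset_seeds[i])
      grm <- compute_grm(pool_freq(ds$obs_pool_freqs))
      ymat <- matrix(ds$phenotypes$value, nrow = scenario$n_families,
                     ncol = scenario$n_replicates,
                     byrow = TRUE)          # phenotypes ordered by family, rep
      fit <- fit_pooled_gblup(ymat, grm, control = control)
      h <- heritabilities(fit, mean_diag = grm$mean_diagonal)
      data.frame(dataset = i, seed = dataset_seeds[i],
                 h2_G = h$h2_G, H2 = if (two_rep) h$H2 else NA_real_,
                 mean_diag = grm$mean_diagonal,
                 mean_offdiag = grm$mean_offdiagonal,
                 sigma2_g = fit$varcomp[["genomic"]],
                 sigma2_f = if (two_rep) fit$varcomp[["family"]] else NA_real_,
                 sigma2_e = fit$varcomp[["residual"]],
                 loglik = fit$loglik, iterations = fit$iterations)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      next
    }
    rows[[i]] <- res
  }
  if (n_fail > 0.2 * n_datasets)
    stop("scenario aborted: ", n_fail, " of ", n_datasets,
         " datasets failed to converge")
  est <- do.call(rbind, rows)
  mc <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v),
      mc_se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  summ <- rbind(h2_G = mc(est$h2_G),
                H2 = if (two_rep) mc(est$H2) else c(NA_real_, NA_real_),
                mean_diag = mc(est$mean_diag),
                mean_offdiag = mc(est$mean_offdiag))
  structure(list(scenario = scenario, n_datasets = n_datasets,
                 n_converged = nrow(est), n_failed = n_fail,
                 estimates = est, mean = summ[, "mean"],
                 mc_se = summ[, "mc_se"], seed = seed,
                 dataset_seeds = dataset_seeds),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  sc <- x$scenario
  cat("scenario_summary: ", x$n_converged, "/", x$n_datasets,
      " datasets (", sc$n_qtl, " QTL, depth ",
      if (is.infinite(sc$depth)) "infinite" else sc$depth, ", ",
      sc$n_replicates, " rep)\n", sep = "")
  tab <- data.frame(mean = round(x$mean, 4), mc_se = round(x$mc_se, 4))
  print(tab)
  invisible(x)
}
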
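#' Simulation scenario for F2 family-pool GBS data
#'
#' Bundles the settings of one simulation scenario: number of families and
#' SNP markers, number of QTL, sequencing depth, phenotype replication and
#' the true heritabilities the phenotype model encodes.
#'
#' With the total genetic variance standardized to 1, the residual and
#' family variances are derived from the target heritabilities:
#' for one replicate per family, `sigma2_e = 1/h2 - 1` (3.0 at h2 = 0.25);
#' for two replicates, the per-plot phenotypic variance is `1/h2` so that
#' `sigma2_f = H2/h2 - 1` (0.5 at H2 = 0.375) and
#' `sigma2_e = 1/h2 - 1 - sigma2_f` (2.5).
#'
#' @param n_families number of F2 family pools (default 500).
#' @param n_snps number of independent SNP markers (default 1000).
#' @param n_qtl number of SNPs acting as QTL (must be <= `n_snps`).
#' @param depth sequencing reads per pool per SNP (positive integer), or
#'   `Inf`/`"infinite"` for noise-free genotypes.
#' @param n_replicates phenotype plots per family, 1 or 2.
#' @param true_narrow_h2 simulated narrow-sense heritability (default 0.25).
#' @param true_broad_h2 simulated broad-sense heritability, used only with
#'   two replicates (default 0.375).
#' @param founder_model how the four founder genome copies behind a family
#'   pool are drawn: `"independent"` (default) draws four independent
#'   Bernoulli(p) copies (pool frequency = Binomial(4, p)/4, expected GRM
#'   diagonal 1); `"inbred_tetraploid"` treats the pool genotype as a
#'   tetraploid made of two gametic pairs, each pair identical by descent
#'   with probability 0.25 — the F2 inbreeding coefficient — giving
#'   expected diagonal 1.25; `"intercross"` models an idealized pair cross
#'   whose two F1 full sibs are intercrossed, so transmissions from a
#'   shared parent are correlated (expected diagonal 1.5). See
#'   [simulate_true_pool_frequencies()].
#' @param seed integer root seed for the dataset.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_families = 500L, n_snps = 1000L, n_qtl = 50L,
                         depth = 5, n_replicates = 1L,
                         true_narrow_h2 = 0.25, true_broad_h2 = 0.375,
                         founder_model = c("independent", "inbred_tetraploid",
                                           "intercross"),
                         seed = 1L) {
  founder_model <- match.arg(founder_model)
  if (n_families < 1) stop("'n_families' must be at least 1")
  if (n_snps < 1) stop("'n_snps' must be at least 1")
  if (n_qtl < 1 || n_qtl > n_snps)
    stop("'n_qtl' must lie in [1, n_snps]; got ", n_qtl, " with ",
         n_snps, " SNPs")
  if (identical(depth, "infinite")) depth <- Inf
  if (!is.infinite(depth) && (depth < 1 || depth != round(depth)))
    stop("'depth' must be a positive integer or infinite")
  if (!n_replicates %in% c(1L, 2L))
    stop("'n_replicates' must be 1 or 2")
  if (true_narrow_h2 <= 0 || true_narrow_h2 > true_broad_h2 ||
      true_broad_h2 >= 1)
    stop("need 0 < true_narrow_h2 <= true_broad_h2 < 1")
  var_plot <- 1 / true_narrow_h2             # per-plot phenotypic variance
  sigma2_f <- if (n_replicates == 2L) var_plot * true_broad_h2 - 1 else 0
  if (sigma2_f < 0) stop("heritability settings imply negative family variance")
  sigma2_e <- var_plot - 1 - sigma2_f
  if (sigma2_e <= 0) stop("heritability settings imply non-positive residual variance")
  structure(list(n_families = as.integer(n_families),
                 n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
                 depth = depth, n_replicates = as.integer(n_replicates),
                 true_narrow_h2 = true_narrow_h2,
                 true_broad_h2 = true_broad_h2,
                 sigma2_f = sigma2_f, sigma2_e = sigma2_e,
                 founder_model = founder_model, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario: ", x$n_families, " families, ", x$n_snps, " SNPs, ",
      x$n_qtl, " QTL, depth ",
      if (is.infinite(x$depth)) "infinite" else x$depth, ", ",
      x$n_replicates, " replicate(s)\n", sep = "")
  cat("  true h2 = ", x$true_narrow_h2,
      if (x$n_replicates == 2L) paste0(", true H2 = ", x$true_broad_h2),
      " (sigma2_f = ", x$sigma2_f, ", sigma2_e = ", x$sigma2_e, ")\n",
      sep = "")
  invisible(x)
}

#' Draw per-SNP population allele frequencies
#'
#' Each SNP's population frequency is drawn independently from a uniform
#' distribution on \[0.05, 0.95\].
#'
#' @param n_snps number of SNPs (non-negative).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_snps`.
#' @export
draw_population_frequencies <- function(n_snps, seed = NULL) {
  if (n_snps < 0) stop("'n_snps' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n_snps, min = 0.05, max = 0.95)
}

#' Simulate true F2 family-pool frequencies
#'
#' An F2 family pool derives from four founder genome copies, so its true
#' allele frequency at a SNP is a multiple of 0.25 — frequencies come in
#' quarters. The options differ in how those four copies are
#' correlated, i.e. in the inbreeding the pool genotype carries:
#' \describe{
#'   \item{`"independent"`}{(default) four independent Bernoulli(p)
#'     copies, Binomial(4, p)/4; variance `p(1-p)/4`, expected GRM
#'     diagonal 1.}
#'   \item{`"inbred_tetraploid"`}{two gametic pairs, the two copies of a
#'     pair identical by descent with probability 0.25, the F2 inbreeding
#'     coefficient; per-SNP variance `0.3125 p(1-p)`, expected diagonal
#'     1.25.}
#'   \item{`"intercross"`}{two F1 full sibs of a single pair cross are
#'     intercrossed; each F1 transmits one random allele of the shared
#'     grandparent on each side, so copies are correlated within a side;
#'     variance `3 p(1-p)/8`, expected diagonal 1.5.}
#' }
#'
#' @param pop_freqs per-SNP population frequencies in \[0, 1\].
#' @param n_families number of families (columns).
#' @param seed optional integer seed.
#' @param founder_model `"independent"`, `"inbred_tetraploid"` or
#'   `"intercross"`.
#' @return SNP x family matrix with values in \{0, 0.25, 0.5, 0.75, 1\}.
#' @export
simulate_true_pool_frequencies <- function(pop_freqs, n_families, seed = NULL,
                                           founder_model = c("independent",
                                                             "inbred_tetraploid",
                                                             "intercross")) {
  founder_model <- match.arg(founder_model)
  pop_freqs <- as.numeric(pop_freqs)
  if (length(pop_freqs) && (min(pop_freqs) < 0 || max(pop_freqs) > 1))
    stop("population frequencies must lie in [0, 1]")
  if (n_families < 0) stop("'n_families' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(pop_freqs)
  if (founder_model == "independent") {
    q <- matrix(stats::rbinom(n * n_families, size = 4L,
                              prob = rep(pop_freqs, times = n_families)) / 4,
                nrow = n, ncol = n_families)
  } else if (founder_model == "inbred_tetraploid") {
    p <- rep(pop_freqs, times = n_families)
    draw <- function() matrix(stats::rbinom(n * n_families, 1L, p), n)
    ibd <- function() matrix(stats::rbinom(n * n_families, 1L, 0.25), n)
    pair <- function() {                # gametic pair, IBD with prob 0.25
      z <- draw(); u <- draw(); b <- ibd()
      z + ifelse(b == 1L, z, u)
    }
    q <- (pair() + pair()) / 4
  } else {
    p <- rep(pop_freqs, times = n_families)
    draw <- function() matrix(stats::rbinom(n * n_families, 1L, p), n)
    a1 <- draw(); a2 <- draw()          # maternal grandparent alleles
    b1 <- draw(); b2 <- draw()          # paternal grandparent alleles
    pick <- function(x, y) {            # one meiosis per F1 per side
      u <- matrix(stats::runif(n * n_families) < 0.5, n)
      ifelse(u, x, y)
    }
    q <- (pick(a1, a2) + pick(a1, a2) + pick(b1, b2) + pick(b1, b2)) / 4
  }
  rownames(q) <- paste0("snp_", seq_len(n))
  colnames(q) <- paste0("fam_", seq_len(n_families))
  q
}

#' Apply binomial sequencing noise to true pool frequencies
#'
#' GBS estimates a pool frequency from `depth` reads: the observed
#' frequency is Binomial(depth, true)/depth. `depth = Inf` (or
#' `"infinite"`) returns the true frequencies unchanged.
#'
#' @param true_pool_freqs SNP x family matrix of true frequencies.
#' @param depth reads per pool per SNP; positive integer or infinite.
#' @param seed optional integer seed.
#' @return Matrix of observed frequencies, same shape and dimnames.
#' @export
sequence_pool_frequencies <- function(true_pool_freqs, depth, seed = NULL) {
  if (identical(depth, "infinite")) depth <- Inf
  if (is.infinite(depth)) return(true_pool_freqs)
  if (depth < 1 || depth != round(depth))
    stop("'depth' must be a positive integer or infinite")
  if (!is.null(seed)) set.seed(seed)
  obs <- matrix(stats::rbinom(length(true_pool_freqs), size = as.integer(depth),
                              prob = true_pool_freqs) / depth,
                nrow = nrow(true_pool_freqs))
  dimnames(obs) <- dimnames(true_pool_freqs)
  obs
}

#' Simulate QTL phenotypes for family pools
#'
#' Chooses `n_qtl` SNPs uniformly without replacement as QTL, draws their
#' effects from a standard normal, forms each family's total genetic value
#' as the effect-weighted sum of its true QTL frequencies, and standardizes
#' the genetic values to empirical variance 1 (mean 0). Phenotypes are then
#' `y = g + e` with one replicate, or `y = g + f + e` with an iid family
#' effect and two replicates; the overall mean is 0 (any constant is
#' absorbed by the fixed mean during REML).
#'
#' @param true_pool_freqs SNP x family matrix of true pool frequencies.
#' @param scenario a [sim_scenario()] supplying `n_qtl`, `n_replicates`,
#'   `sigma2_f` and `sigma2_e`.
#' @param seed optional integer seed.
#' @return List with `qtl_indices`, `qtl_effects`, `genetic_values`
#'   (variance exactly 1 across families) and `phenotypes`, a data frame
#'   with columns `family`, `rep`, `value`.
#' @export
simulate_phenotypes <- function(true_pool_freqs, scenario, seed = NULL) {
  if (!inherits(scenario, "sim_scenario"))
    stop("'scenario' must be a sim_scenario object")
  n_snps <- nrow(true_pool_freqs)
  n_fam <- ncol(true_pool_freqs)
  if (scenario$n_qtl > n_snps)
    stop("n_qtl (", scenario$n_qtl, ") exceeds the ", n_snps,
         " available SNPs")
  if (!is.null(seed)) set.seed(seed)
  qtl <- sort(sample.int(n_snps, scenario$n_qtl))
  effects <- stats::rnorm(scenario$n_qtl)
  g_raw <- drop(crossprod(true_pool_freqs[qtl, , drop = FALSE], effects))
  if (stats::var(g_raw) <= 0)
    stop("raw genetic values have zero variance; cannot standardize ",
         "(degenerate pool frequencies at the sampled QTL)")
  g <- (g_raw - mean(g_raw)) / stats::sd(g_raw)
  fam_ids <- colnames(true_pool_freqs)
  if (is.null(fam_ids)) fam_ids <- paste0("fam_", seq_len(n_fam))
  if (scenario$n_replicates == 1L) {
    e <- stats::rnorm(n_fam, sd = sqrt(scenario$sigma2_e))
    pheno <- data.frame(family = fam_ids, rep = 1L, value = g + e,
                        stringsAsFactors = FALSE)
  } else {
    f <- stats::rnorm(n_fam, sd = sqrt(scenario$sigma2_f))
    e <- stats::rnorm(2L * n_fam, sd = sqrt(scenario$sigma2_e))
    pheno <- data.frame(family = rep(fam_ids, each = 2L),
                        rep = rep(1:2, times = n_fam),
                        value = rep(g + f, each = 2L) + e,
                        stringsAsFactors = FALSE)
  }
  list(qtl_indices = qtl, qtl_effects = effects, genetic_values = g,
       phenotypes = pheno)
}

#' Simulate one complete family-pool GBS dataset
#'
#' Runs the full generative chain of one scenario: population frequencies,
#' true pool frequencies, binomially sequenced observed frequencies, QTL
#' phenotypes. Each stage consumes its own sub-seed, drawn once from the
#' root seed in a fixed order (frequencies, pool genotypes, reads,
#' phenotypes), so a stage can be regenerated independently from the
#' recorded sub-seed.
#'
#' @param scenario a [sim_scenario()].
#' @param seed root seed; defaults to `scenario$seed`.
#' @return An object of class `sim_dataset`: the scenario, `pop_freqs`,
#'   `true_pool_freqs`, `obs_pool_freqs`, QTL truth, `genetic_values`,
#'   `phenotypes` and the `stage_seeds` used.
#' @export
simulate_pool_dataset <- function(scenario, seed = scenario$seed) {
  if (!inherits(scenario, "sim_scenario"))
    stop("'scenario' must be a sim_scenario object")
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  pop <- draw_population_frequencies(scenario$n_snps, seed = stage_seeds[1L])
  truef <- simulate_true_pool_frequencies(pop, scenario$n_families,
                                          seed = stage_seeds[2L],
                                          founder_model = scenario$founder_model)
  obs <- sequence_pool_frequencies(truef, scenario$depth,
                                   seed = stage_seeds[3L])
  ph <- simulate_phenotypes(truef, scenario, seed = stage_seeds[4L])
  structure(c(list(scenario = scenario, seed = seed,
                   stage_seeds = stage_seeds, pop_freqs = pop,
                   true_pool_freqs = truef, obs_pool_freqs = obs), ph),
            class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `true_freqs.tsv`, `obs_freqs.tsv`, `phenotypes.tsv` and a
#' `truth.json` sidecar (scenario settings, QTL indices and effects,
#' variance settings) into `dir`.
#'
#' @param dataset a `sim_dataset` from [simulate_pool_dataset()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_pool_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "sim_dataset")) stop("'dataset' must be a sim_dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_frequency_matrix(pool_freq(dataset$true_pool_freqs),
                         file.path(dir, "true_freqs.tsv"))
  write_frequency_matrix(pool_freq(dataset$obs_pool_freqs),
                         file.path(dir, "obs_freqs.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  sc <- dataset$scenario
  truth <- list(scenario = unclass(sc)[c("n_families", "n_snps", "n_qtl",
                                         "n_replicates", "true_narrow_h2",
                                         "true_broad_h2", "sigma2_f",
                                         "sigma2_e", "founder_model")],
                depth = if (is.infinite(sc$depth)) "infinite" else sc$depth,
                seed = dataset$seed,
                stage_seeds = dataset$stage_seeds,
                qtl_indices = dataset$qtl_indices,
                qtl_effects = dataset$qtl_effects)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dput(truth, file = file.path(dir, "truth.json"))
  }
  invisible(dir)
}
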
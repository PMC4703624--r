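test_that("population frequencies are uniform on [0.05, 0.95]", {
  expect_length(draw_population_frequencies(0), 0)
  p <- draw_population_frequencies(1000, seed = 7)
  expect_gte(min(p), 0.05)
  expect_lte(max(p), 0.95)
  # moments of U(0.05, 0.95) at n = 1e5: mean 0.5, variance 0.9^2/12
  p <- draw_population_frequencies(1e5, seed = 8)
  se_mean <- sqrt(0.0675 / 1e5)
  expect_lt(abs(mean(p) - 0.5), 3 * se_mean)
  se_var <- sqrt(2 / 1e5) * 0.0675   # approximate SE of a sample variance
  expect_lt(abs(var(p) - 0.0675), 3 * se_var)
  expect_identical(draw_population_frequencies(10, seed = 1),
                   draw_population_frequencies(10, seed = 1))
  expect_error(draw_population_frequencies(-1), "non-negative")
})

test_that("true pool frequencies come in quarters with binomial moments", {
  p <- c(0, 0.3, 0.5, 0.9)
  q <- simulate_true_pool_frequencies(p, n_families = 4000, seed = 3)
  expect_true(all(q %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_true(all(q[1, ] == 0))
  # P(pool frequency = 0.5 | p = 0.5) = C(4,2)/16 = 6/16
  prop_half <- mean(q[3, ] == 0.5)
  expect_lt(abs(prop_half - 6 / 16), 3 * sqrt(6 / 16 * 10 / 16 / 4000))
  # per-SNP mean ~ p, variance ~ p(1-p)/4
  for (i in 2:4) {
    v_true <- p[i] * (1 - p[i]) / 4
    expect_lt(abs(mean(q[i, ]) - p[i]), 3 * sqrt(v_true / 4000))
    expect_lt(abs(var(q[i, ]) - v_true), 3 * sqrt(2 / 4000) * v_true * 2)
  }
  expect_error(simulate_true_pool_frequencies(c(0.2, 1.4), 10),
               "\\[0, 1\\]")
})

test_that("founder models encode the intended pool-genotype variance", {
  p <- rep(0.5, 400)
  for (fm in c("independent", "inbred_tetraploid", "intercross")) {
    q <- simulate_true_pool_frequencies(p, 500, seed = 5, founder_model = fm)
    expect_true(all(q %in% c(0, 0.25, 0.5, 0.75, 1)))
    mult <- c(independent = 1, inbred_tetraploid = 1.25, intercross = 1.5)[[fm]]
    v_true <- mult * 0.25 * 0.25      # scale * p(1-p)/4 at p = 0.5
    v_obs <- mean(apply(q, 1, var))
    expect_lt(abs(v_obs - v_true), 4 * sqrt(2 / (500 * 400)) * v_true)
  }
})

test_that("sequencing noise is binomial and unbiased", {
  q <- matrix(0.5, 200, 50)
  q[1, ] <- 0
  obs <- sequence_pool_frequencies(q, depth = 5, seed = 9)
  expect_true(all(obs[1, ] == 0))
  expect_true(all(obs %in% ((0:5) / 5)))
  # E[obs | true] = true, var = q(1-q)/depth
  n <- 199 * 50
  expect_lt(abs(mean(obs[-1, ]) - 0.5), 3 * sqrt(0.05 / n))
  expect_lt(abs(var(as.vector(obs[-1, ])) - 0.05), 3 * sqrt(2 / n) * 0.05 * 2)
  expect_identical(sequence_pool_frequencies(q, Inf), q)
  expect_identical(sequence_pool_frequencies(q, "infinite"), q)
  expect_error(sequence_pool_frequencies(q, 0), "positive integer")
  expect_error(sequence_pool_frequencies(q, -3), "positive integer")
})

test_that("phenotype simulation standardizes genetic values and hits the target variances", {
  sc <- sim_scenario(n_families = 400, n_snps = 200, n_qtl = 20,
                     depth = 5, n_replicates = 1, seed = 2)
  q <- simulate_true_pool_frequencies(draw_population_frequencies(200, 1), 400,
                                      seed = 2)
  ph <- simulate_phenotypes(q, sc, seed = 3)
  expect_equal(var(ph$genetic_values), 1, tolerance = 1e-12)
  expect_equal(mean(ph$genetic_values), 0, tolerance = 1e-12)
  expect_length(ph$qtl_indices, 20)
  expect_false(anyDuplicated(ph$qtl_indices) > 0)
  expect_equal(nrow(ph$phenotypes), 400)
  # per-family phenotype variance ~ 1/h2 = 4 (genetic 1 + residual 3)
  expect_lt(abs(var(ph$phenotypes$value) - 4), 3 * sqrt(2 / 399) * 4)

  sc2 <- sim_scenario(n_families = 2000, n_snps = 200, n_qtl = 20,
                      depth = 5, n_replicates = 2, seed = 4)
  q2 <- simulate_true_pool_frequencies(draw_population_frequencies(200, 4),
                                       2000, seed = 5)
  ph2 <- simulate_phenotypes(q2, sc2, seed = 6)
  expect_equal(nrow(ph2$phenotypes), 4000)
  y1 <- ph2$phenotypes$value[ph2$phenotypes$rep == 1]
  y2 <- ph2$phenotypes$value[ph2$phenotypes$rep == 2]
  # within-family covariance of replicate pairs = genetic 1 + family 0.5
  expect_lt(abs(cov(y1, y2) - 1.5), 3 * sqrt((4 * 4 + 1.5^2) / 1999))
})

test_that("degenerate genetic values raise rather than divide by zero", {
  q <- matrix(0.5, 10, 50)    # constant frequencies -> zero genetic variance
  sc <- sim_scenario(n_families = 50, n_snps = 10, n_qtl = 2, depth = 5,
                     seed = 1)
  expect_error(simulate_phenotypes(q, sc, seed = 1), "zero variance")
})

test_that("dataset simulation is reproducible and internally consistent", {
  sc <- sim_scenario(n_families = 30, n_snps = 50, n_qtl = 5, depth = 5,
                     n_replicates = 2, seed = 99)
  d1 <- simulate_pool_dataset(sc)
  d2 <- simulate_pool_dataset(sc)
  expect_identical(d1$obs_pool_freqs, d2$obs_pool_freqs)
  expect_identical(d1$phenotypes, d2$phenotypes)
  d3 <- simulate_pool_dataset(sc, seed = 100)
  expect_false(identical(d1$obs_pool_freqs, d3$obs_pool_freqs))
  # observed frequencies are multiples of 1/depth
  expect_true(all(d1$obs_pool_freqs %in% ((0:5) / 5)))
  # stages can be regenerated from their recorded sub-seeds
  redo <- sequence_pool_frequencies(d1$true_pool_freqs, 5,
                                    seed = d1$stage_seeds[3])
  expect_identical(redo, d1$obs_pool_freqs)
})

test_that("scenario validation rejects inconsistent settings", {
  expect_error(sim_scenario(n_qtl = 2000, n_snps = 1000), "n_qtl")
  expect_error(sim_scenario(depth = 0), "depth")
  expect_error(sim_scenario(n_replicates = 3), "replicates")
  expect_error(sim_scenario(true_narrow_h2 = 0.5, true_broad_h2 = 0.4),
               "true_narrow_h2")
  sc <- sim_scenario(depth = "infinite")
  expect_true(is.infinite(sc$depth))
  # derived variance settings: sigma2_e = 3 (1 rep), f = 0.5 / e = 2.5 (2 rep)
  expect_equal(sim_scenario(n_replicates = 1)$sigma2_e, 3)
  sc2 <- sim_scenario(n_replicates = 2)
  expect_equal(sc2$sigma2_f, 0.5)
  expect_equal(sc2$sigma2_e, 2.5)
})

test_that("a simulated dataset round-trips through the plain-text writers", {
  sc <- sim_scenario(n_families = 8, n_snps = 12, n_qtl = 3, depth = 5,
                     seed = 7)
  ds <- simulate_pool_dataset(sc)
  dir <- withr::local_tempdir()
  write_pool_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("true_freqs.tsv", "obs_freqs.tsv", "phenotypes.tsv", "truth.json")))))
  back <- read_frequency_matrix(file.path(dir, "obs_freqs.tsv"))
  expect_equal(back$values, ds$obs_pool_freqs)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph$value, ds$phenotypes$value)
})
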
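# Balanced one-way layout: REML variance components have the closed-form
# ANOVA solution sigma2_e = MSE, sigma2_group = (MSB - MSE)/r when MSB > MSE.
test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  set.seed(40)
  q <- 12; r <- 4
  for (case in 1:3) {
    grp <- gl(q, r)
    y <- rnorm(q, sd = 1.5)[grp] + rnorm(q * r)
    ms <- anova(lm(y ~ grp))
    msb <- ms[["Mean Sq"]][1]; mse <- ms[["Mean Sq"]][2]
    if (msb <= mse) next
    Z <- model.matrix(~ 0 + grp)
    fit <- reml_fit(y, random = list(group = list(Z = Z)))
    expect_equal(unname(fit$varcomp[["residual"]]), mse, tolerance = 1e-6)
    expect_equal(unname(fit$varcomp[["group"]]), (msb - mse) / r,
                 tolerance = 1e-6)
  }
})

test_that("AI-REML matches direct numerical likelihood maximization", {
  set.seed(41)
  n <- 40
  G <- crossprod(matrix(rnorm(n * n), n)) / n
  diag(G) <- diag(G) + 0.1
  y <- drop(chol(0.8 * G + 1.2 * diag(n)) %*% rnorm(n)) + 2
  X <- matrix(1, n, 1)
  fit <- reml_fit(y, X = X, random = list(genomic = list(Z = diag(n), K = G)))
  A <- list(G)
  opt <- optim(c(0.5, 0.5),
               function(lt) -reml_loglik_direct(exp(lt), y, X, A),
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  expect_lte(abs(fit$loglik - (-opt$value)), 1e-4)
  expect_gte(fit$loglik, -opt$value - 1e-6)   # AI-REML found an optimum
  expect_equal(unname(fit$varcomp), exp(opt$par), tolerance = 1e-2)
})

test_that("diagonal and dense likelihood kernels agree", {
  set.seed(42)
  n <- 30
  d <- sort(runif(n, 0, 3), decreasing = TRUE)
  y <- rnorm(n, sd = sqrt(1 + d))
  X <- matrix(1, n, 1)
  f1 <- reml_fit(y, X, random = list(g = diag(d, n)))
  f2 <- reml_fit(y, X, random = list(g = diag(d, n)),
                 control = reml_control(force_dense = TRUE))
  expect_equal(f1$kernel, "diagonal")
  expect_equal(f2$kernel, "dense")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-5)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-4)
})

test_that("the REML objective never decreases over accepted iterations", {
  set.seed(43)
  fam <- gl(25, 2)
  y <- rnorm(25, sd = 1.2)[fam] + rnorm(50)
  fit <- reml_fit(y, random = list(family = list(Z = model.matrix(~ 0 + fam))))
  expect_true(all(diff(fit$trajectory$loglik) > -1e-9))
  expect_true(fit$converged)
})

test_that("a null genomic component lands at the boundary", {
  # with sigma2_g truly 0 roughly half the REML estimates sit on the
  # boundary; check the typical (median) estimate over a few datasets and
  # that each optimum dominates an interior alternative
  n <- 80
  ests <- vapply(1:5, function(i) {
    set.seed(44 + i)
    G <- crossprod(matrix(rnorm(n * n), n)) / n
    y <- rnorm(n)                        # pure noise
    fit <- reml_fit(y, random = list(genomic = list(Z = diag(n), K = G)))
    ll_alt <- reml_loglik_direct(c(0.3 * var(y), 0.7 * var(y)), y,
                                 matrix(1, n, 1), list(G))
    expect_gte(fit$loglik, ll_alt - 1e-8)
    fit$varcomp[["genomic"]] / var(y)
  }, numeric(1))
  expect_lt(median(ests), 0.02)
})

test_that("likelihood is invariant to fixed-effect reparameterization", {
  set.seed(45)
  fam <- gl(20, 2)
  y <- rnorm(20)[fam] + rnorm(40)
  Z <- model.matrix(~ 0 + fam)
  x2 <- rep(c(1, -1), 20)
  f1 <- reml_fit(y, X = cbind(1, x2), random = list(family = list(Z = Z)))
  # same column space in a new basis X2 = X B with det(B) = 2: estimates are
  # invariant and the log-likelihood shifts by the constant -log|det B|
  f2 <- reml_fit(y, X = cbind(2, x2 - 5),
                 random = list(family = list(Z = Z)))
  expect_equal(f1$loglik, f2$loglik + log(2), tolerance = 1e-6)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-4)
  # an actually singular design errors
  expect_error(reml_fit(y, X = cbind(1, x2, x2),
                        random = list(family = list(Z = Z))), "singular")
})

test_that("estimates are invariant to observation order with iid structure", {
  set.seed(46)
  fam <- gl(15, 3)
  y <- rnorm(15, sd = 1.3)[fam] + rnorm(45)
  Z <- model.matrix(~ 0 + fam)
  perm <- sample(45)
  f1 <- reml_fit(y, random = list(family = list(Z = Z)))
  f2 <- reml_fit(y[perm], random = list(family = list(Z = Z[perm, ])))
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("iid-model estimates agree with an independent lme4 fit", {
  skip_if_not_installed("lme4")
  set.seed(47)
  fam <- gl(30, 3)
  y <- rnorm(30, sd = 1.1)[fam] + rnorm(90)
  fit <- reml_fit(y, random = list(family = list(Z = model.matrix(~ 0 + fam))))
  lfit <- lme4::lmer(y ~ 1 + (1 | fam), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(unname(fit$varcomp[["family"]]), vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(fit$varcomp[["residual"]]), vc$vcov[2], tolerance = 1e-4)
})

test_that("GBLUP recovers the simulated variance components on average", {
  # noiseless pool frequencies, true sigma2_g = 1, sigma2_e = 3
  ests <- t(vapply(1:15, function(i) {
    sc <- sim_scenario(n_families = 150, n_snps = 400, n_qtl = 400,
                       depth = "infinite", n_replicates = 1, seed = 500 + i)
    ds <- simulate_pool_dataset(sc)
    g <- compute_grm(pool_freq(ds$obs_pool_freqs))
    ymat <- matrix(ds$phenotypes$value, ncol = 1)
    fit <- poolherit:::fit_pooled_gblup(ymat, g)
    fit$varcomp
  }, numeric(2)))
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  # finite-marker shrinkage (150 families / 400 markers) leaves a small
  # downward bias on sigma2_g, so allow 3 MC SE + 10% of the truth
  expect_lt(abs(mean(ests[, "genomic"]) - 1), 3 * mc_se["genomic"] + 0.1)
  expect_lt(abs(mean(ests[, "residual"]) - 3), 3 * mc_se["residual"] + 0.3)
})

test_that("non-convergence raises an error carrying the trajectory", {
  set.seed(48)
  fam <- gl(10, 2)
  y <- rnorm(10)[fam] + rnorm(20)
  err <- tryCatch(
    reml_fit(y, random = list(family = list(Z = model.matrix(~ 0 + fam))),
             control = reml_control(max_iter = 1, n_em = 1,
                                    tol_loglik = 0, tol_param = 0)),
    error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "did not converge")
  expect_s3_class(err$trajectory, "data.frame")
})
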
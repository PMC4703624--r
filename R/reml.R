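#' Control settings for the AI-REML fitter
#'
#' @param max_iter iteration cap (default 200).
#' @param tol_param convergence when the largest relative parameter change
#'   drops below this (default 1e-8).
#' @param tol_loglik convergence when the REML log-likelihood change drops
#'   below this (default 1e-9).
#' @param n_em number of initial EM iterations before switching to
#'   average-information steps (default 2; EM is slow but monotone-stable).
#' @param min_varcomp_frac floor for variance components as a fraction of
#'   the phenotypic variance (default 1e-8); negative proposals are
#'   truncated here.
#' @param max_halvings step halvings attempted when a step lowers the
#'   likelihood before falling back to EM (default 10).
#' @param force_dense skip the diagonal fast path even when every random
#'   covariance contribution is diagonal (for testing; default `FALSE`).
#' @param verbose print the iteration trajectory.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(max_iter = 200L, tol_param = 1e-8,
                         tol_loglik = 1e-9, n_em = 2L,
                         min_varcomp_frac = 1e-8, max_halvings = 10L,
                         force_dense = FALSE, verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol_param = tol_param,
                 tol_loglik = tol_loglik, n_em = as.integer(n_em),
                 min_varcomp_frac = min_varcomp_frac,
                 max_halvings = as.integer(max_halvings),
                 force_dense = isTRUE(force_dense),
                 verbose = isTRUE(verbose)),
            class = "reml_control")
}

## ---- likelihood kernels ----------------------------------------------------
## Both kernels evaluate, at a parameter vector theta (one variance per random
## term plus the residual, in that order), the REML log-likelihood
##   l = -1/2 [ log|V| + log|X'V^-1 X| + y'Py ],   V = sum_c theta_c A_c,
## P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1, together with tr(P A_c),
## y'P A_c P y and the average-information matrix
##   AI_cd = 1/2 (A_c P y)' P (A_d P y).

reml_kernel_dense <- function(theta, A, X, y) {
  n <- length(y)
  nc <- length(A)
  V <- diag(theta[nc + 1L], n)
  for (c in seq_len(nc)) V <- V + theta[c] * A[[c]]
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  Vinv <- chol2inv(cv)
  logdetV <- 2 * sum(log(diag(cv)))
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  cx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cx)) return(NULL)
  logdetX <- 2 * sum(log(diag(cx)))
  XtVXinv <- chol2inv(cx)
  P <- Vinv - VinvX %*% XtVXinv %*% t(VinvX)
  Py <- drop(P %*% y)
  loglik <- -0.5 * (logdetV + logdetX + sum(y * Py))
  beta <- drop(XtVXinv %*% crossprod(VinvX, y))
  np <- nc + 1L
  trPA <- yPAPy <- numeric(np)
  U <- matrix(0, n, np)                   # columns A_c P y
  for (c in seq_len(nc)) {
    trPA[c] <- sum(P * A[[c]])            # both symmetric
    u <- drop(A[[c]] %*% Py)
    U[, c] <- u
    yPAPy[c] <- sum(Py * u)
  }
  trPA[np] <- sum(diag(P))
  U[, np] <- Py
  yPAPy[np] <- sum(Py * Py)
  PU <- P %*% U
  AI <- 0.5 * crossprod(U, PU)
  list(loglik = loglik, trPA = trPA, yPAPy = yPAPy, AI = AI,
       beta = beta, Py = Py)
}

## Diagonal kernel: every A_c is diagonal with diagonal a[, c] (residual
## column of ones appended); O(n p^2) per evaluation.
reml_kernel_diag <- function(theta, a, X, y) {
  v <- drop(a %*% theta)
  if (min(v) <= 0) return(NULL)
  w <- 1 / v
  Xw <- X * w
  XtVX <- crossprod(X, Xw)
  cx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cx)) return(NULL)
  XtVXinv <- chol2inv(cx)
  beta <- drop(XtVXinv %*% crossprod(Xw, y))
  Py <- w * y - drop(Xw %*% beta)
  loglik <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cx))) + sum(y * Py))
  pmul <- function(u) w * u - drop(Xw %*% (XtVXinv %*% crossprod(X, w * u)))
  np <- ncol(a)
  trPA <- yPAPy <- numeric(np)
  U <- a * Py                              # column c = a_c * Py = A_c P y
  for (c in seq_len(np)) {
    trPA[c] <- sum(a[, c] * w) -
      sum(XtVXinv * crossprod(X, X * (a[, c] * w * w)))
    yPAPy[c] <- sum(Py * U[, c])
  }
  PU <- apply(U, 2L, pmul)
  AI <- 0.5 * crossprod(U, PU)
  list(loglik = loglik, trPA = trPA, yPAPy = yPAPy, AI = AI,
       beta = beta, Py = Py)
}

## ---- fitter ----------------------------------------------------------------

#' Fit a variance-component mixed model by AI-REML
#'
#' Restricted maximum likelihood for the Gaussian mixed model
#' `y = X b + sum_c Z_c u_c + e`, `u_c ~ N(0, K_c sigma2_c)`,
#' `e ~ N(0, I sigma2_e)`, by the average-information algorithm: the first
#' iterations (and any step that would lower the restricted likelihood)
#' use monotone EM updates, after which quasi-Newton steps use the average
#' of observed and expected information. Variance components are
#' constrained non-negative by truncation at a small floor.
#'
#' When every random term contributes a diagonal covariance `Z K Z'` (for
#' example after rotating a GBLUP model to the eigenbasis of its GRM) an
#' exact O(n) likelihood evaluation is used automatically.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default a column of ones); must
#'   have full column rank.
#' @param random named list of random terms; each term is a list with `Z`
#'   (n x q incidence matrix) and optionally `K` (q x q symmetric
#'   covariance; identity when omitted). A term may instead be given
#'   directly as its n x n covariance contribution `A = Z K Z'`.
#' @param start optional starting values, one per random term plus the
#'   residual; default splits the phenotypic variance equally.
#' @param control a [reml_control()].
#' @return An object of class `reml_fit`: `varcomp` (named vector, last
#'   element `"residual"`), `vcov` (inverse average-information matrix),
#'   `loglik`, `beta`, `iterations`, `converged`, `trajectory`.
#' @examples
#' set.seed(1)
#' fam <- gl(20, 4)
#' y <- rnorm(20)[fam] + rnorm(80)
#' fit <- reml_fit(y, random = list(family = list(Z = model.matrix(~ 0 + fam))))
#' fit$varcomp
#' @export
reml_fit <- function(y, X = NULL, random = list(), start = NULL,
                     control = reml_control()) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least two observations")
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design matrix is singular (rank ", qr(X)$rank,
         " < ", ncol(X), " columns)")
  if (length(random) && is.null(names(random)))
    names(random) <- paste0("u", seq_along(random))
  A <- lapply(random, function(term) {
    if (is.matrix(term)) {
      if (nrow(term) != n || ncol(term) != n)
        stop("a random term given as a matrix must be its n x n covariance")
      return((term + t(term)) / 2)
    }
    Z <- as.matrix(term$Z)
    if (nrow(Z) != n) stop("random-term Z must have one row per observation")
    if (is.null(term$K)) return(tcrossprod(Z))
    K <- as.matrix(term$K)
    if (nrow(K) != ncol(Z) || ncol(K) != ncol(Z))
      stop("random-term K must be square with dimension ncol(Z)")
    (Z %*% K %*% t(Z) + t(Z %*% K %*% t(Z))) / 2
  })
  nc <- length(A)
  np <- nc + 1L
  comp_names <- c(names(A), "residual")
  varP <- stats::var(y)
  if (varP <= 0) stop("response has zero variance")
  floor_v <- control$min_varcomp_frac * varP

  is_diag <- function(M) all(abs(M[row(M) != col(M)]) < 1e-12)
  use_diag <- !control$force_dense && (nc == 0L || all(vapply(A, is_diag,
                                                              logical(1L))))
  if (use_diag) {
    a <- cbind(if (nc) vapply(A, diag, numeric(n)) else NULL, rep(1, n))
    a[a < 0 & a > -1e-10] <- 0           # roundoff from eigen rotations
    if (nc && min(a) < 0)
      stop("diagonal covariance contribution with negative entries")
    evalfun <- function(theta) reml_kernel_diag(theta, a, X, y)
  } else {
    evalfun <- function(theta) reml_kernel_dense(theta, A, X, y)
  }

  theta <- if (is.null(start)) rep(varP / np, np) else as.numeric(start)
  if (length(theta) != np)
    stop("'start' must have ", np, " values (", nc, " random + residual)")
  theta <- pmax(theta, floor_v)
  ## effective level counts for the EM denominators
  q_em <- c(if (nc) vapply(seq_len(nc), function(c) {
    term <- random[[c]]
    if (is.matrix(term)) n else ncol(as.matrix(term$Z))
  }, numeric(1L)) else NULL, n)

  st <- evalfun(theta)
  if (is.null(st)) stop("likelihood not evaluable at the starting values")
  traj <- data.frame(iter = 0L, loglik = st$loglik,
                     t(stats::setNames(theta, comp_names)))
  converged <- FALSE
  iter <- 0L
  em_step <- function(theta, st)
    pmax(theta + theta^2 * (st$yPAPy - st$trPA) / q_em, floor_v)
  while (iter < control$max_iter) {
    iter <- iter + 1L
    use_em <- iter <= control$n_em
    proposal <- NULL
    if (!use_em) {
      score <- -0.5 * (st$trPA - st$yPAPy)
      delta <- tryCatch(solve(st$AI, score), error = function(e) NULL)
      if (!is.null(delta)) proposal <- pmax(theta + delta, floor_v)
    }
    if (is.null(proposal)) proposal <- em_step(theta, st)
    new_st <- evalfun(proposal)
    ## guard: fall back to step-halving, then EM, if the likelihood drops
    h <- 0L
    while ((is.null(new_st) || new_st$loglik < st$loglik - 1e-10) &&
           h < control$max_halvings) {
      h <- h + 1L
      proposal <- pmax(theta + (proposal - theta) / 2, floor_v)
      new_st <- evalfun(proposal)
    }
    if (is.null(new_st) || new_st$loglik < st$loglik - 1e-10) {
      proposal <- em_step(theta, st)
      new_st <- evalfun(proposal)
      if (is.null(new_st)) break
    }
    dl <- new_st$loglik - st$loglik
    dp <- max(abs(proposal - theta) / pmax(abs(theta), 1e-12 * varP))
    theta <- proposal
    st <- new_st
    traj <- rbind(traj, data.frame(iter = iter, loglik = st$loglik,
                                   t(stats::setNames(theta, comp_names))))
    if (control$verbose)
      message(sprintf("iter %3d  logL %.8f  %s", iter, st$loglik,
                      paste(signif(theta, 6), collapse = " ")))
    if (abs(dl) < control$tol_loglik || dp < control$tol_param) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- simpleError(paste0("AI-REML did not converge in ", iter,
                               " iterations"))
    cond$trajectory <- traj
    stop(cond)
  }
  vc <- tryCatch(solve(st$AI), error = function(e) NULL)
  if (is.null(vc)) {
    warning("average-information matrix is singular; ",
            "asymptotic covariance unavailable")
    vc <- matrix(NA_real_, np, np)
  }
  dimnames(vc) <- list(comp_names, comp_names)
  structure(list(varcomp = stats::setNames(theta, comp_names), vcov = vc,
                 loglik = st$loglik, beta = st$beta, iterations = iter,
                 converged = converged, trajectory = traj,
                 n_obs = n, kernel = if (use_diag) "diagonal" else "dense"),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit (", x$n_obs, " obs, ", x$iterations,
      " iterations, logL = ", round(x$loglik, 4), ")\n", sep = "")
  se <- sqrt(pmax(diag(x$vcov), 0))
  print(data.frame(estimate = round(x$varcomp, 6), se = round(se, 6)))
  invisible(x)
}

## ---- balanced GBLUP rotation ----------------------------------------------
## Exact orthogonal reduction of the simulation models to a diagonal
## covariance form. One replicate: y = mu + g + e with V = G sg + I se;
## rotating by the eigenvectors U of G gives diagonal V. Two balanced
## replicates: the per-family mean contrasts (y1 + y2)/sqrt(2) carry
## covariance 2G sg + 2I sf + I se and the difference contrasts
## (y1 - y2)/sqrt(2) carry I se; both blocks are diagonalized by U.
## REML is invariant under this orthonormal transformation.
fit_pooled_gblup <- function(y_by_family, G, control = reml_control()) {
  Gm <- if (inherits(G, "pool_grm")) G$G else as.matrix(G)
  nf <- nrow(Gm)
  y_by_family <- as.matrix(y_by_family)
  if (nrow(y_by_family) != nf)
    stop("phenotype rows must match GRM dimension")
  n_rep <- ncol(y_by_family)
  ee <- eigen((Gm + t(Gm)) / 2, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  Ut <- t(ee$vectors)
  if (n_rep == 1L) {
    yt <- drop(Ut %*% y_by_family[, 1L])
    Xt <- Ut %*% matrix(1, nf, 1L)
    fit <- reml_fit(yt, X = Xt,
                    random = list(genomic = diag(d, nf)),
                    control = control)
  } else if (n_rep == 2L) {
    ym <- drop(Ut %*% ((y_by_family[, 1L] + y_by_family[, 2L]) / sqrt(2)))
    yd <- (y_by_family[, 1L] - y_by_family[, 2L]) / sqrt(2)
    yt <- c(ym, yd)
    Xt <- rbind(Ut %*% matrix(sqrt(2), nf, 1L), matrix(0, nf, 1L))
    Ag <- diag(c(2 * d, rep(0, nf)), 2L * nf)
    Af <- diag(c(rep(2, nf), rep(0, nf)), 2L * nf)
    fit <- reml_fit(yt, X = Xt,
                    random = list(genomic = Ag, family = Af),
                    control = control)
  } else {
    stop("balanced rotation supports 1 or 2 replicates")
  }
  fit
}
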
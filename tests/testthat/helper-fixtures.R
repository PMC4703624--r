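# Small fixtures built in code, shared across test files.

# a 5 SNP x 4 family frequency matrix with depths and one missing cell
make_small_pfm <- function() {
  set.seed(42)
  v <- matrix(round(runif(20), 2), 5, 4)
  d <- matrix(sample(1:30, 20, replace = TRUE), 5, 4)
  v[2, 3] <- NA
  d[2, 3] <- 0
  pool_freq(v, depths = d)
}

# naive double-loop GRM oracle: G_jk = sum_i M_ij M_ik / K
grm_oracle <- function(values) {
  means <- rowMeans(values, na.rm = TRUE)
  M <- values - means
  M[is.na(M)] <- 0
  K <- 0.25 * sum(means * (1 - means))
  nf <- ncol(values)
  G <- matrix(0, nf, nf)
  for (j in seq_len(nf))
    for (k in seq_len(nf))
      G[j, k] <- sum(M[, j] * M[, k]) / K
  G
}

# explicitly-coded REML log-likelihood for the oracle comparison:
# l = -1/2 (log|V| + log|X'V^-1 X| + y'Py) maximized by a generic optimizer
reml_loglik_direct <- function(theta, y, X, A_list) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (c in seq_along(A_list)) V <- V + theta[c] * A_list[[c]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(t(y) %*% P %*% y))
}
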
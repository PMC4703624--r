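## Recognized variance-component roles. A reml_fit's components are matched
## by name: "genomic" (GRM term), "family" (iid family term), "pop"
## (parent-population term), "residual". Absent terms contribute 0.

herit_weights <- function(fit, mean_diag, ww_diag) {
  vc <- fit$varcomp
  w <- stats::setNames(rep(1, length(vc)), names(vc))
  if ("genomic" %in% names(vc)) w["genomic"] <- mean_diag
  if ("pop" %in% names(vc)) w["pop"] <- ww_diag
  w
}

#' Total phenotypic variance implied by a variance-component fit
#'
#' Evaluates `var(y) = meandiag(G) * sigma2_g + sigma2_f + WW' * sigma2_p
#' + sigma2_e`: the genomic component enters through the average diagonal
#' of the GRM used, and the parent-population component through the
#' diagonal of `WW'` (2 when every family has two parents from two parent
#' populations). Components absent from the fit contribute 0.
#'
#' @param fit a [reml_fit()] whose components are named among `"genomic"`,
#'   `"family"`, `"pop"`, `"residual"`.
#' @param mean_diag average diagonal of the GRM behind the `"genomic"`
#'   term (non-negative).
#' @param ww_diag diagonal value of `WW'` for the parent-population term
#'   (default 2).
#' @return The scalar total variance.
#' @export
total_variance <- function(fit, mean_diag, ww_diag = 2) {
  if (!inherits(fit, "reml_fit")) stop("'fit' must be a reml_fit")
  if (mean_diag < 0) stop("'mean_diag' must be non-negative")
  sum(herit_weights(fit, mean_diag, ww_diag) * fit$varcomp)
}

#' Heritability estimators for family-pool phenotypes
#'
#' From a variance-component fit, computes
#' \describe{
#'   \item{`h2_G`}{`sigma2_g / var(y)` — narrow-sense genomic heritability;}
#'   \item{`h2_G_PP`}{`(sigma2_g + WW' sigma2_p) / var(y)` — narrow sense
#'     including the parent-population variance;}
#'   \item{`H2`}{`(meandiag(G) sigma2_g + WW' sigma2_p + sigma2_f) / var(y)`
#'     — broad sense, all family-associated variance.}
#' }
#' with `var(y)` from [total_variance()]. The GRM scale factor in `H2`'s
#' numerator is the mean diagonal of the GRM actually used. Standard
#' errors come from the delta method on the inverse average-information
#' matrix (see [heritability_se()]).
#'
#' @inheritParams total_variance
#' @return An object of class `herit_estimates`: list with `h2_G`,
#'   `h2_G_PP`, `H2`, their `se`, `var_y`, `mean_diag`, `ww_diag`, and the
#'   `var_y_decomposition`.
#' @examples
#' # a converged fit with sigma2_g = 1, sigma2_f = 0.5, sigma2_e = 2.5 and
#' # unit mean GRM diagonal gives h2_G = 0.25 and H2 = 0.375
#' @export
heritabilities <- function(fit, mean_diag, ww_diag = 2) {
  if (!inherits(fit, "reml_fit")) stop("'fit' must be a reml_fit")
  vc <- fit$varcomp
  w <- herit_weights(fit, mean_diag, ww_diag)
  var_y <- sum(w * vc)
  if (var_y <= 0) stop("total variance is not positive (", var_y, ")")
  num <- function(roles, weights) {
    z <- stats::setNames(rep(0, length(vc)), names(vc))
    present <- intersect(roles, names(vc))
    z[present] <- weights[match(present, roles)]
    z
  }
  g <- if ("genomic" %in% names(vc)) vc[["genomic"]] else 0
  p <- if ("pop" %in% names(vc)) vc[["pop"]] else 0
  f <- if ("family" %in% names(vc)) vc[["family"]] else 0
  h2_G <- g / var_y
  h2_G_PP <- (g + ww_diag * p) / var_y
  H2 <- (mean_diag * g + ww_diag * p + f) / var_y
  ## numerator coefficient vectors for the delta method
  n_h2G <- num("genomic", 1)
  n_h2GPP <- num(c("genomic", "pop"), c(1, ww_diag))
  n_H2 <- num(c("genomic", "pop", "family"), c(mean_diag, ww_diag, 1))
  se <- c(h2_G = ratio_se(n_h2G, w, vc, fit$vcov),
          h2_G_PP = ratio_se(n_h2GPP, w, vc, fit$vcov),
          H2 = ratio_se(n_H2, w, vc, fit$vcov))
  structure(list(h2_G = h2_G, h2_G_PP = h2_G_PP, H2 = H2, se = se,
                 var_y = var_y, mean_diag = mean_diag, ww_diag = ww_diag,
                 var_y_decomposition = w * vc),
            class = "herit_estimates")
}

#' @export
print.herit_estimates <- function(x, ...) {
  est <- c(h2_G = x$h2_G, h2_G_PP = x$h2_G_PP, H2 = x$H2)
  out <- data.frame(estimate = round(est, 4), se = round(x$se, 4))
  cat("heritability estimates (var(y) = ", round(x$var_y, 4),
      ", mean GRM diagonal = ", round(x$mean_diag, 4), ")\n", sep = "")
  print(out)
  invisible(x)
}

## delta-method SE of (n'theta)/(d'theta) given cov(theta) = C
ratio_se <- function(n_vec, d_vec, theta, C) {
  if (anyNA(C)) return(NA_real_)
  N <- sum(n_vec * theta)
  D <- sum(d_vec * theta)
  grad <- (n_vec * D - N * d_vec) / D^2
  v <- drop(crossprod(grad, C %*% grad))
  if (is.na(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Delta-method standard errors of the heritability estimators
#'
#' Each heritability is a ratio of linear combinations of the variance
#' components; its standard error is obtained by the delta method from the
#' asymptotic covariance of the REML estimates (the inverse
#' average-information matrix).
#'
#' @inheritParams total_variance
#' @return Named numeric vector with elements `h2_G`, `h2_G_PP`, `H2`
#'   (`NA` when the covariance matrix is unavailable).
#' @export
heritability_se <- function(fit, mean_diag, ww_diag = 2) {
  heritabilities(fit, mean_diag, ww_diag)$se
}
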
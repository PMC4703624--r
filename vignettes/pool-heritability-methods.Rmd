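---
title: "Methods: genomic heritability from family-pool GBS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic heritability from family-pool GBS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolherit)
```

## The measurement and its error structure

A family pool is a bulk DNA sample from many plants of one family. GBS
sequencing of the pool yields, at every biallelic SNP, a count of
alternate-allele reads out of a total read depth, so the pool "genotype"
is an allele-frequency estimate rather than a discrete call. Two layers of
randomness matter:

1. **Genetic sampling.** An F2 family derives from four founder genome
   copies, so its true pool frequency at a SNP is a multiple of 0.25.
2. **Read sampling.** With depth $d$, the observed frequency is
   $\hat q = \mathrm{Binomial}(d, q)/d$: unbiased
   ($E[\hat q \mid q] = q$) but with conditional variance $q(1-q)/d$.

Everything in this package follows from how that second layer propagates
into relationship matrices and variance components.

## The pool-level GRM and its depth-dependent diagonal

With $X_{ij}$ the frequency of SNP $i$ in family $j$, SNP means
$\bar X_i$ over non-missing families, centered matrix
$M_{ij} = X_{ij} - \bar X_i$ (missing cells set to 0, i.e. mean
imputation), the GRM is

$$G = \frac{M'M}{K}, \qquad K = 0.25 \sum_i \bar X_i (1 - \bar X_i),$$

the pool-frequency analogue of VanRaden's method 1. $K$ equals the summed
expected per-SNP variance of F2 pool frequencies when the four founder
copies are independent, so for noise-free, non-inbred pools
$E[G_{jj}] \approx 1$. Read sampling adds $E[q_i(1-q_i)]/d$ to each SNP's
realized variance. For independent founder copies
$E[q(1-q)] = \tfrac{3}{4}p(1-p)$, hence

$$E[G_{jj}] \approx 1 + \frac{3}{d},$$

while off-diagonals are essentially unbiased: the measurement errors of
two different pools are independent, so their cross-products average to
zero. This asymmetry — inflated diagonals, stable off-diagonals — is the
mechanism behind the downward bias of genomic heritability at low depth,
and the test suite checks it directly on simulated matrices.

Missing data: a cell observed at depth 0 carries no estimate. Mean
imputation makes such cells contribute 0 to $M'M$; the optional
missing-rate correction rescales each element by a pairwise constant
$K_{jk} = 0.25\sum_{i \in \text{obs}(j) \cap \text{obs}(k)} \bar
X_i(1-\bar X_i)$, so that relationships between poorly genotyped families
are not shrunk toward zero by the zero-imputed cells. It is off by
default on complete data, where it is exactly a no-op (which the tests
verify).

A centered GRM is singular (one zero eigenvalue from the centering).
`invert_grm()` raises the smallest eigenvalue to
`repair_factor` $\times$ the second smallest — "just below" it; the
factor defaults to 0.99, a value chosen once as "just below" without
further tuning — and inverts in the eigenbasis,
$G^{-1} = E \Lambda_{\text{rep}}^{-1} E'$. The REML fitter itself works
with covariance matrices, not
their inverses, so the repaired inverse is provided for interoperability
with downstream mixed-model software.

## The mixed model and AI-REML

Plot phenotypes are modelled as
$y = Xt + Zg + Zf + Wp + e$ with trial blocks fixed,
$g \sim N(0, G\sigma^2_g)$, $f \sim N(0, I\sigma^2_f)$,
$p \sim N(0, I\sigma^2_p)$, $e \sim N(0, I\sigma^2_e)$. `reml_fit()`
implements restricted maximum likelihood with average-information
updates:

* the first 2 iterations (configurable) use EM updates
  $\theta_c \leftarrow \theta_c + \theta_c^2\,(y'PA_cPy -
  \mathrm{tr}(PA_c))/q_c$, which are slow but stable far from the
  optimum;
* subsequent steps solve $\mathrm{AI}\,\delta = s$ with
  $\mathrm{AI}_{cd} = \tfrac12 y'PA_cPA_dPy$ and score
  $s_c = -\tfrac12(\mathrm{tr}(PA_c) - y'PA_cPy)$;
* any step that would lower the restricted likelihood is halved up to 10
  times and then replaced by an EM step, so accepted iterations are
  monotone (a property the tests assert on the stored trajectory);
* negative proposals are truncated at $10^{-8} \times$ the phenotypic
  variance, giving boundary estimates instead of negative components;
* convergence is declared when the largest relative parameter change
  falls below $10^{-8}$ or the log-likelihood change below $10^{-9}$,
  with a cap of 200 iterations; non-convergence is an error that carries
  the iteration trajectory.

Starting values split the phenotypic variance equally across components.
The asymptotic covariance of the estimates is the inverse AI matrix at
the optimum, and heritability standard errors follow by the delta method
on each ratio; they are labelled as delta-method values in the output,
since profile-likelihood intervals would be a different (and more
expensive) choice.

Identifiability: with one plot per family the iid family effect is
completely confounded with the residual, so the pipeline drops it (with a
message) and the simulation fits use $y = \mu + g + e$; with two plots
the two-replicate model $y = \mu + g + f + e$ is identifiable.

**Computation.** Problem sizes here are at most a few thousand
observations, so the likelihood is evaluated by dense Cholesky
factorizations; traces $\mathrm{tr}(PA_c)$ use the elementwise identity
$\sum_{uv} P_{uv}(A_c)_{uv}$ for symmetric matrices. For the balanced
simulation models the fitter is fed an exactly rotated problem: with
$G = UDU'$, rotating a one-replicate GBLUP model by $U'$ (and, with two
balanced replicates, first forming per-family mean and difference
contrasts, whose covariances are $2GD\sigma^2_g$-diagonal and residual
respectively) makes every covariance contribution diagonal. REML is
invariant under orthonormal transformation, and the tests confirm that
the rotated (O(n) per evaluation) and dense fits agree to numerical
precision. Small negative eigenvalues from roundoff are clamped to zero
before rotation.

## The simulator: what it emulates and what it does not

`simulate_pool_dataset()` reproduces the generative chain of the
simulation study: per-SNP population frequencies uniform on
$[0.05, 0.95]$; true pool frequencies in quarters; binomial read noise at
depth 5, 15, 25 (or none, `depth = "infinite"`); QTL drawn uniformly
without replacement with standard-normal effects; total genetic values
standardized to variance exactly 1; phenotypes with one replicate
($\sigma^2_e = 3$, so $h^2 = 0.25$) or two replicates
($\sigma^2_f = 0.5$, $\sigma^2_e = 2.5$, so $h^2 = 0.25$,
$H^2 = 0.375$). The residual and family variances are derived from the
target heritabilities with genetic variance 1; the overall mean is fixed
at 0 since any constant is absorbed by the fixed mean. Each dataset uses
one root seed from which per-stage sub-seeds are drawn in a fixed order
(population frequencies, pool genotypes, reads, phenotypes), so any stage
can be regenerated independently.

Deliberately **not** modelled, matching the simulation being reproduced:
linkage or ancestral LD between markers (SNPs are independent), selection,
finite pool size (the pool frequency is the expected F2 frequency, not a
sample over 200–500 plants), sequencing error on top of binomial
sampling, and genotype-by-environment structure. Passing tests therefore
demonstrate correctness of the estimation machinery under these idealized
conditions, not robustness to LD, sequencing error or finite-pool noise
in real GBS data.

### The founder model — an open design point

How the four founder copies behind a pool are correlated determines the
expected GRM diagonal, and the natural descriptions disagree. F2
families are 25 % inbred, and by analogy with the diploid
self-relationship $1 + F$ one expects diagonals of 1.25; yet the exact
two-F1 full-sib intercross pedigree gives pool-frequency variance
$\tfrac38 p(1-p)$ (diagonal 1.5), while four independent copies give
$\tfrac14 p(1-p)$ (diagonal 1.0) — no exact pedigree yields 1.25. The
package therefore implements three switchable options in
`simulate_true_pool_frequencies()`:

| option | construction | var(q) / p(1−p) | E diag |
|---|---|---|---|
| `independent` | Binomial(4, p)/4 | 0.25 | 1.0 |
| `inbred_tetraploid` | two gametic pairs, each IBD w.p. 0.25 | 0.3125 | 1.25 |
| `intercross` | exact two-F1 full-sib intercross | 0.375 | 1.5 |

All three were run against the published simulation benchmark that the
acceptance tests target. The `independent` model reproduces the
benchmark means at every depth once the finite-marker shrinkage of a
500-family / 1000-SNP design is accounted for; the other two undershoot
at depths 15–25 by 0.04–0.06. `independent` is therefore the default,
and the 1.25-diagonal expectation applies only under the
`inbred_tetraploid` option.

## Filters and depth bins

SNP filtering drops loci with mean read depth above 60 (suspected
plastid/repeat reads) and loci whose mean frequency lies outside
$[0.02, 0.98]$; the bounds are inclusive because removal is stated
strictly ("less than"/"greater than"). The frequency rule is applied to
the per-SNP **mean** frequency across families — the same quantity the
GRM centers on — since per-family application is not specified. Mean
depth counts zero-depth cells: depth 0 is a real sequencing outcome of a
SNP. Families with more than 50 % missing calls are removed. Depth bins
follow a $(lo, hi]$ convention with the first bin closed on the left so
that depth 0 is binned; the shared-edge convention is not stated in the
source and is configurable. Filter order is depth, then frequency, then
families, then binning, and every filter returns a report whose counts
reconcile (checked by tests).

## Problem sizes and tolerances

The Monte Carlo scenario runs use the simulated study design of 500
families and 1000 SNPs, with 50 datasets per scenario in
`scripts/acceptance.R` and 25 datasets per cell in the test suite,
comparing means within three combined (benchmark + own Monte Carlo)
standard errors. Property tests use
small instances (10×10 GRMs against a brute-force double-loop oracle,
≤ 50-observation REML problems against direct Nelder–Mead maximization of
an explicitly coded restricted likelihood, with agreement required to
$10^{-4}$ in log-likelihood). Scenario datasets whose fit fails to
converge are excluded and counted, with more than 20 % failures aborting
the scenario; in practice failures are not observed at these sizes.

## Known limitations

* The AI-REML implementation handles dense covariance structures up to a
  few thousand observations; it has no sparse machinery and is not meant
  for individual-level national-evaluation scale.
* Heritability standard errors are asymptotic; near the variance
  boundary ($\sigma^2 \approx 0$) the delta method understates
  uncertainty and the AI matrix can be near-singular, in which case SEs
  are reported as `NA` with a warning.
* The empirical-style pipeline assumes family ids are consistent across
  frequency, depth and phenotype inputs and errors otherwise; it does
  not attempt id harmonization.
* Simulated depth is constant across SNPs and pools within a scenario;
  real GBS depth is overdispersed, so real-data diagonal inflation at a
  given average depth is stronger than the $1 + 3/d$ rule of thumb.
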
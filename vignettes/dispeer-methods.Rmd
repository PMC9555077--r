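---
title: "Graph-informed penalized regression for cortical region data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-informed penalized regression for cortical region data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispeer)
```

# The problem

Studies relating brain structure to cognition often regress a scalar outcome
(say, a vocabulary-comprehension score) on region-level cortical measurements
— one predictor per parcellated region — while adjusting for demographics.
With tens of correlated region predictors and a few hundred subjects,
ordinary least squares is noisy, and plain ridge regression ignores what we
know about the brain: regions that are structurally connected, or spatially
close on the cortical surface, tend to carry similar associations.

`dispeer` implements a generalized-ridge (Tikhonov) estimator whose penalty
encodes both kinds of side information. The model is

$$y = X\beta + Zb + \varepsilon, \qquad \varepsilon \sim N(0,
\sigma_\varepsilon^2 I_n),$$

where $X$ ($n \times m$) holds unpenalized covariates (e.g. gender, age) and
$Z$ ($n \times p$) the region-level predictors. The coefficients $b$ solve

$$\min_{b, \beta}\; \|y - X\beta - Zb\|_2^2 +
b^\top\!\left(\lambda_C \tilde Q_C + \lambda_D \tilde Q_{\tilde D} +
\lambda_R I\right) b,$$

with $\tilde Q_C$ the normalized graph Laplacian of a structural-connectivity
adjacency matrix, $\tilde Q_{\tilde D}$ the normalized Laplacian of a
distance-derived proximity matrix, and an identity (ridge) term. A Laplacian
penalty $b^\top Q b$ shrinks *differences* between coefficients of linked
regions rather than the coefficients themselves, so connected or nearby
regions are encouraged to act similarly.

# From distances to a penalty

Pairwise region distances $d_{ij}$ (straight-line between centroids, or
geodesic along the folded cortical surface) are first max-normalized,
$\tilde d_{ij} = d_{ij} / \max_{k,l} d_{kl}$, removing brain-size scale
(`normalize_distances()`). A Gaussian similarity kernel then converts
distance into proximity,

$$a_{ij} = \exp(-h\,\tilde d_{ij}^2), \quad i \ne j, \qquad a_{ii} = 0,$$

(`proximity_from_distance()`). The bandwidth $h > 0$ controls contrast: small
$h$ makes all regions look similar; large $h$ keeps only the closest pairs
proximate. Defaults of $h = 5$ for Euclidean distances and $h = 100$ for
geodesic-style distances keep the proximity matrix informative — with
Euclidean centroid distances large $h$ washes out the differentiation among
the many mid-range pairs, while geodesic distances tolerate (and benefit
from) a sharper, more nearly binary kernel.

Both the connectivity adjacency $A_C$ and the proximity matrix $A_{\tilde D}$
enter the penalty through the normalized Laplacian

$$\tilde Q_{ij} = \begin{cases} 1 & i = j\\
-a_{ij}/\sqrt{s_i s_j} & i \ne j\end{cases}, \qquad s_i = \sum_j a_{ij},$$

whose spectrum lies in $[0, 2]$ regardless of edge-weight scale — this puts
the two information sources on a comparable footing so that the weights
$\lambda_C, \lambda_D$ are interpretable. Connectivity matrices are sparse
(most region pairs share no direct white-matter tract) and may contain
isolated regions; an isolated node receives an identity row (diagonal 1,
off-diagonals 0), so its coefficient falls back to pure ridge shrinkage and
the matrix stays positive semi-definite. Proximity matrices are dense (every
kernel value is positive), so isolation never arises there.

A remark on the quadratic form: the identity
$b^\top Q b = \sum_{i<j} a_{ij}(b_i - b_j)^2$ holds for the *unnormalized*
Laplacian $Q = S - A$ (and the test suite verifies it there); the penalty
actually used is the normalized Laplacian above, whose quadratic form is the
analogous degree-scaled sum. Similarly, max-normalization of distances is a
pure rescaling — it cannot create or remove zero distances — and is applied
exactly as written.

# Tuning the penalty weights by marginal likelihood

The estimator is the posterior mode of the mixed model in which
$b \sim N(0, \sigma_\varepsilon^2 B_\lambda^{-1})$ with
$B_\lambda = \lambda_C \tilde Q_C + \lambda_D \tilde Q_{\tilde D} +
\lambda_R I$. After projecting out $X$
($y_P = P y$, $\tilde Z = P Z$ with $P = I - X(X^\top X)^{-1}X^\top$,
`project_out_fixed()`), the marginal distribution of the projected response
is

$$y_P \sim N\!\left(0,\; \sigma_\varepsilon^2\,(\tilde Z B_\lambda^{-1}
\tilde Z^\top + I_n)\right),$$

and the weights are chosen to maximize this likelihood with
$\sigma_\varepsilon^2$ profiled out analytically:
$\hat\sigma_\varepsilon^2 = \tfrac{1}{n} y_P^\top (\tilde Z B_\lambda^{-1}
\tilde Z^\top + I_n)^{-1} y_P$. The $B_\lambda^{-1}$ form of the covariance
is the one consistent with the prior above and with the closed-form solution

$$\hat b = (\tilde Z^\top \tilde Z + B_\lambda)^{-1} \tilde Z^\top y_P,
\qquad \hat\beta = (X^\top X)^{-1} X^\top (y - Z\hat b),$$

which is what the package implements throughout. Likelihood evaluation uses
the determinant and quadratic-form identities that reduce everything to
Cholesky factorizations of $p \times p$ matrices
($\log\det(\tilde Z B^{-1}\tilde Z^\top + I) = \log\det(B + \tilde Z^\top
\tilde Z) - \log\det B$, and the matching Woodbury identity for the
quadratic form), so cost scales with the number of regions, not subjects;
the tests check the values against a dense $n \times n$ Gaussian-density
oracle.

The ridge weight $\lambda_R$ is kept above a small floor ($10^{-6}$ by
default, configurable in `dispeer_control()`): graph Laplacians are singular
(the constant vector is always in their null space), and the added identity
keeps $B_\lambda$ invertible so the marginal likelihood is defined — without
it, likelihood-based tuning of a Laplacian-only penalty is ill-posed.

**Optimization.** The profiled objective is smooth but not convex in the
weights. `estimate_lambdas()` runs box-constrained L-BFGS-B on the
$\log(\lambda + \epsilon)$ scale (the offset $\epsilon = 10^{-8}$ lets the
Laplacian weights reach exactly zero) from five deterministic starting
points log-spaced over $[10^{-4}, 10^{2}]$, with an upper bound of $10^6$
per weight and an objective tolerance of $10^{-8}$. Among starts whose
objectives tie within tolerance, the solution with the smallest total
penalty $\sum\lambda$ is returned, making the fit deterministic. On small
instances the attained optimum is verified in the tests to dominate a
$10^3$-point weight grid.

Special cases come from switching penalties off: connectivity + ridge only
(`method = "ripeer"`), ridge only (`"ridge"`), and unpenalized joint least
squares (`"ols"`). These reductions are exact and tested: with
$\lambda_D = 0$ the three-penalty solution equals the two-penalty one, with
all Laplacian weights zero it is classical ridge, and as all weights vanish
it tends to OLS of $y_P$ on $\tilde Z$.

# The simulation framework

`generate_structure()`, `generate_replicate()` and `run_experiment()`
reproduce the estimator-comparison design at configurable scale. The
generative model per replicate is

* $Z$ with iid $N(0, I_p)$ rows, $X$ with iid $N(0, I_m)$ rows, $\beta = 0$;
* $b \sim N(0, \sigma_b^2 B_{true}^{-1})$ with
  $B_{true} = r_C\,Q_{C,true} + (1 - r_C)\,Q_{D,true} + r_R I$, so $r_C$
  dials how much of the coefficient structure is connectivity- versus
  proximity-driven;
* $y = X\beta + Zb + \varepsilon$, $\varepsilon \sim N(0,
  \sigma_\varepsilon^2 I_n)$.

Defaults are the study conditions: $n = 400$, $m = 2$, signal
$\sigma_b^2 \in \{0.01, 0.1\}$ against noise
$\sigma_\varepsilon^2 \in \{1, 5\}$, $r_C \in \{0.1, 0.5, 0.9\}$, 100
replicates, and a dissimilarity of 0.25 between the true connectivity used
to generate $b$ and the observed connectivity used to fit — fitting always
sees a corrupted graph, while the distance matrix (measurable with modern
imaging tools essentially exactly) is used as-is, with only its bandwidth
$h$ potentially misspecified.

$r_R$ in $B_{true}$ is needed for invertibility but its magnitude is
otherwise inconsequential; the default 0.01 is small enough that the two
graph terms dominate. Accuracy is summarized by the relative mean squared
error $\mathrm{rMSE}(\hat b) = \|\hat b - b\|_2^2 / \|b\|_2^2$ (1 for the
all-zero estimator), reported as the median over replicates, the robust
summary appropriate for its right-skewed distribution across replicates.
The bias–variance decomposition works on the per-replicate errors
$\hat b_r - b_r$ per coefficient, using the population-divisor variance so
that MSE = variance + squared bias holds exactly by construction; both the
per-coefficient table and the coefficient sums are reported.

**Connectivity corruption.** The dissimilarity between observed and true
connectivity counts differing entries over twice the number of positive
entries of the truth. The corruption mechanism toggles
$k = \mathrm{round}(t \cdot E)$ uniformly chosen symmetric pairs ($E$ =
positive entries of the truth): positive entries are deleted, zero entries
receive a weight resampled from the truth's positive weights. This keeps
the corrupted matrix a plausible connectivity matrix (same weight
distribution, partial overlap with the truth) and hits the nearest
achievable dissimilarity — a multiple of $1/E$ — exactly.

**What the synthetic structure emulates — and what it does not.** Real
hemisphere analyses use tractography-derived connectivity over 27–29
Desikan-Killiany regions grouped into connected blocks of at least four
regions, with centroid (Euclidean) or surface (geodesic) distances. The
generator emulates the block sparsity (block-diagonal adjacency, a connected
ring backbone per block plus random within-block edges at density 0.5,
weights uniform on $[0.5, 1.5]$) and the two distance flavours (uniform
coordinates in a 60 mm cube; or points on an 80 mm-radius spherical cap with
great-circle distances, which preserves the geodesic $\ge$ chord ordering of
a folded surface). It does *not* reproduce tractography weight
distributions, the spatial autocorrelation of real centroid layouts, or the
mesh-derived geodesic distances of an actual cortex, so simulation results
demonstrate the estimator's behaviour under the stated generative model, not
performance guarantees on any particular imaging dataset. Defaults were
fixed once from these considerations.

At desk scale (12 regions, $n = 200$, 50 replicates, $r_C = 0.1$,
$\sigma_b^2/\sigma_\varepsilon^2 = 0.01$ — the regime where proximity
carries most of the structure and the signal is weak) the expected ordering
is reproduced: the distance-informed fit attains the lowest median rMSE,
the connectivity-only fit is second, ridge is worst, and the advantage of
the distance-informed fit comes from lower bias at comparable variance.
The acceptance script (`scripts/acceptance.R`) recomputes exactly this
experiment. The same framework exposes a bandwidth-sensitivity mode
(`h_fit` differing from the generating `h`); with `h_fit` off by a factor
of two the median rMSE degrades only mildly (the suite checks a $\le 20\%$
relative increase), consistent with the kernel's gradual effect on the
Laplacian.

# Application-layer preparation and inference

For cortical volume analyses, `normalize_volumes()` forms region volume as
thickness $\times$ area and divides by the subject's total hemispheric
volume (rows sum to 1 exactly), removing overall brain-size differences;
`standardize()` centres and scales columns using the population ($1/n$)
variance so "mean 0, variance 1" is exact rather than approximate.

`bootstrap_fit()` resamples subjects with replacement and refits the whole
pipeline — including re-estimation of the penalty weights — per resample,
forming non-adjusted percentile confidence intervals per coefficient. A
fixed-weight fast mode (`refit_lambda = FALSE`) is available when the
resampling cost matters. P-values use the two-sided sign-proportion rule
$p = 2\min(\Pr(\hat b^* \le 0), \Pr(\hat b^* \ge 0))$, floored at
$1/n_{boot}$ — the natural companion of percentile intervals, agreeing with
interval-excludes-zero significance at matching levels. The default of
1,000 resamples balances interval stability against the cost of full
refits; intervals are deterministic given the seed. The intervals are
deliberately per-coefficient and unadjusted for multiplicity; simultaneous
bands are out of scope.

Calibration: on pure-noise fixtures the 95% intervals exclude zero for
about 5% of coefficients (the suite checks the count against a 99%
binomial acceptance region; heavy shrinkage under pure noise makes the
empirical rate err on the conservative side, around 3% in the packaged
runs).

# Numerical choices and edge cases

* All-zero distance matrices (coincident coordinates) are rejected at
  normalization rather than silently producing a degenerate kernel.
* Non-positive kernel bandwidths, rank-deficient $X$, all-zero reference
  connectivity (undefined dissimilarity), and constant columns passed to
  `standardize()` are rejected with messages naming the offending input.
* The dissimilarity count uses strict `|difference| > 0` at machine
  precision: connectivity matrices are stored inputs, not computed values,
  so no epsilon is warranted.
* Matrix I/O is comma-separated with an optional label header (tabs
  accepted on read) and validates symmetry to an absolute $10^{-10}$ by
  default, reporting the first offending entry.
* Every stochastic entry point takes an explicit seed; experiments derive
  one sub-seed per replicate from the master seed, so runs are bitwise
  reproducible and individual replicates can be reproduced in isolation.

Problem sizes in the packaged tests and acceptance script (12 regions,
$n = 200$, 50 replicates; bootstrap at 200 resamples on 60 subjects) are
the package's chosen desk-scale defaults for verifying the method's
qualitative behaviour; the full-scale conditions ($p \approx 30$,
$n = 400$, 100 replicates, 1,000 resamples) remain the defaults of
`simulation_config()` and `bootstrap_fit()`.

# Known limitations

* Tuning uses plain maximum likelihood; a REML variant is not provided.
* Cross-validated tuning is not provided (marginal likelihood is the
  package's mechanism).
* Sparsity-inducing penalties (e.g. lasso) are out of scope.
* The mapping between the prior variance $\sigma_b^2$ of the generative
  model and the estimation parameterization is absorbed into the penalty
  weights; the weights are estimated, not the variance ratio itself.
* Geodesic distances are consumed as matrices; computing them from cortical
  meshes is upstream of this package.
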
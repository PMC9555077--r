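# dispeer

Penalized linear regression for brain-region data that uses **two sources of
anatomical side information** in the penalty: structural connectivity between
cortical regions and their spatial proximity on the cortex.

## The problem and the model

Regressing a cognition score on region-level cortical measurements (one
predictor per parcellated region, demographics adjusted for) is
ill-conditioned at typical study sizes: tens of correlated predictors, a few
hundred subjects. Ridge regression stabilizes the fit but treats all regions
as exchangeable. Anatomy says they are not — regions joined by white-matter
tracts, or lying close together on the cortical surface, tend to relate to
the outcome similarly.

`dispeer` fits the model `y = Xβ + Zb + ε` (X unpenalized, e.g. gender and
age; Z the region predictors) by Tikhonov regularization,

```
min over b, β of  ||y − Xβ − Zb||² + bᵀ (λ_C Q̃_C + λ_D Q̃_D + λ_R I) b
```

where `Q̃_C` is the normalized graph Laplacian of the structural-connectivity
adjacency matrix, `Q̃_D` the normalized Laplacian of a proximity matrix
obtained from pairwise region distances through the Gaussian kernel
`a_ij = exp(−h d̃_ij²)` (distances max-normalized to [0, 1]), and `λ_R I` a
ridge term that keeps the combined penalty invertible. Laplacian penalties
shrink *differences* between coefficients of linked regions. The three
weights are not hand-tuned: they maximize the marginal likelihood of the
equivalent mixed model with prior `b ~ N(0, σ²_ε B_λ⁻¹)`, with the error
variance profiled out analytically. Connectivity-only (`ripeer`), plain
`ridge` and `ols` fits are nested special cases.

The package also ships the full evaluation machinery: a seeded synthetic-data
generator (block-structured sparse connectivity, cortex-like distances, the
structured coefficient prior), relative-MSE comparison of the estimators with
bias–variance decomposition, and subject-resampling bootstrap confidence
intervals and p-values for the penalized coefficients.

## Worked example

```r
library(dispeer)

# structural inputs for one synthetic "hemisphere" of 12 regions
st <- generate_structure(structure_config(p = 12, seed = 1))
QC <- normalized_laplacian(st$connectivity)
Dn <- normalize_distances(st$distance)
QD <- normalized_laplacian(proximity_from_distance(Dn, h = 5))

# one synthetic dataset: weak signal, structure mostly from proximity
cfg <- simulation_config(p = 12, n = 200, r_C = 0.1, sigma2_b = 0.01,
                         sigma2_eps = 1, n_reps = 1, seed = 42)
set.seed(42)
repl <- generate_replicate(cfg, QC, QD)

fit <- fit_dispeer(repl$data, QC = QC, QD = QD, method = "dispeer")
fit
#> Penalized regression fit (method: dispeer)
#>   12 penalized, 2 unpenalized coefficients
#>   lambda_C = 23.49, lambda_D = 23.97, lambda_R = 1.575
#>   sigma2_eps = 1.104, loglik = -304.4332, converged: TRUE

round(rmse(fit$b_hat, repl$b_true), 4)
#> [1] 0.1319
ridge <- fit_dispeer(repl$data, method = "ridge")
round(rmse(ridge$b_hat, repl$b_true), 4)
#> [1] 0.1602
```

The fitted weights say the likelihood found both graphs informative
(`lambda_C`, `lambda_D` both large relative to `lambda_R`); the estimated
noise variance is close to the generating value 1; and on this replicate the
graph-informed fit recovers the coefficients with a relative MSE of 0.13
versus 0.16 for ridge — the kind of gain the simulation study quantifies
systematically (`run_experiment()` repeats this comparison over seeded
replicates and reports median rMSE and the bias–variance split per method).

For inference on real-style data, `normalize_volumes()` and `standardize()`
prepare thickness × area volume predictors, and `bootstrap_fit()` gives
non-adjusted 95% percentile intervals, p-values and significance flags per
region.

A thin command-line front end over these functions is installed at
`inst/cli/dispeer.R` with subcommands `build-penalty`, `fit`, `simulate`,
`bootstrap` and `make-fixture`.

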
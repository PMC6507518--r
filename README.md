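# aiptw: augmented IPTW for clustered data with practical positivity violations

`aiptw` estimates average causal effects from clustered observational
data — the motivating application is evaluating teacher-preparation
pathways through student test-score gains collected across many
schools — when treatment is assigned within clusters and can be taken as
ignorable *given* the cluster, but many realized clusters contain only
treated or only control units (a *practical positivity violation*).

## The model and the estimators

Potential outcomes follow a two-level random coefficient model

    Y_ik(1) = β1 + b_k1 + ε_ik(1)      (b_k1, b_k0) ~ N(0, Ω),
    Y_ik(0) = β0 + b_k0 + ε_ik(0)      ε ~ N(0, σ²_ε),

with Ω parameterized by (σ0, σ1, ρ). The estimand is Δ = β1 − β0. The
within-cluster propensity is the treated share π̂_k = n_k1/n_k, and each
unit gets the inverse-probability weight

    w_ik = t · c/π̂_k + (1 − t) · (1 − c)/(1 − π̂_k),   c = N1/N.

When π̂_k ∈ {0, 1} the cluster carries no within-cluster contrast and the
weighted analysis is biased if violating is correlated with the cluster
effects. The package provides four estimators of (β0, β1, Δ):

- **`iptw_orig()`** — weighted ML fit on the full sample;
- **`iptw_trim()`** — the same after discarding violating clusters
  (changes the target population, inflates variance);
- **`aiptw()`** with model `"satc"` or `"rsatc"` — *augmented* IPTW:
  a cluster-average-treatment corrected outcome model (the cluster mean
  T̄_k enters as a Mundlak-type covariate) is fit to the original data,
  each violating cluster receives one pseudo-unit carrying the predicted
  missing-arm outcome, and the weighted fit is run on the augmented
  sample with propensities recomputed as if the pseudo-unit were
  observed; keeps the original estimand and stays consistent under
  violation;
- **`aiptw_nonparametric()`** — the cluster-average contrast combining
  within-cluster arm-mean differences with the model predictions.

Standard errors: robust cluster sandwich (`robust_sandwich()`) for the
IPTW estimators; cluster bootstrap with full-pipeline refitting
(`cluster_bootstrap()`, default B = 30) for the AIPTW estimators.

A calibrated simulation engine generates study-like data: treatment
follows a latent index c1 + c2·b_k0 + c3·b_k1 + c4·ζ_k + ξ_ik whose
coefficients are solved (`calibrate_assignment()`) to hit targets for
the treatment rate p, the treatment/random-effect correlations (r0, r1),
and the expected fraction of violating clusters.
`run_replications()`/`reproduce_table()` compute the Monte Carlo
bias/SE/coverage summaries per estimator.

## Worked example

Generate one dataset from the shipped high-violation preset (K = 150
schools, sizes 1–19, β = (35, 40), σ0 = σ1 = 8, ρ = 0.8, σε = 45,
r0 = r1 = 0.4, p = 0.3, 80% violating clusters) and compare the plain
and augmented analyses:

```r
library(aiptw)
config <- scenario_preset("setting1_80")
coeffs <- calibrate_assignment(config)
d <- generate_dataset(config, coeffs, seed = 42)

iptw_orig(d)
#> iptw_orig estimate (150 clusters, 121 violating)
#>   beta0 = 29.8574, beta1 = 42.8002, delta = 12.9428
#> sigma0 = 8.7083, sigma1 = 12.6244, rho = 1.0000, sigma_eps = 37.7394

est <- aiptw(d, model = "satc")
est
#> aiptw_satc estimate (150 clusters, 121 violating)
#>   beta0 = 32.4399, beta1 = 44.5965, delta = 12.1565
#> sigma0 = 9.5083, sigma1 = 2.1434, rho = 1.0000, sigma_eps = 37.3465

se <- cluster_bootstrap(d, function(b) aiptw(b, "satc"), B = 30, seed = 1)
se
#> cluster_bootstrap covariance (B = 30): se(beta0) = 2.0384,
#>   se(beta1) = 6.5231, se(delta) = 6.3954
confidence_interval(est$delta_hat, se$se_delta)
#>      lower      upper
#> -0.3781831 24.6912740
```

The true values here are β0 = 35, β1 = 40, Δ = 5. The unweighted-arm
pull of the violating clusters drags the IPTW-orig control mean down to
29.9 (a −15% bias); augmentation pulls it back toward 32.4, and across
replications the augmented estimator is unbiased (see the Monte Carlo
section of the vignette). The wide interval reflects the genuine
information loss when 80% of clusters carry no within-cluster contrast.

A thin command-line wrapper covers the same pipeline
(`inst/cli/aiptw`): `simulate --config scenario.yaml --seed 1 --out
data.csv`, `fit --input data.csv --method aiptw-satc --se bootstrap`,
and `mc-table --table 2 --reps 300`.

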
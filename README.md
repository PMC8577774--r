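# spde: semiparametric maximum likelihood density estimation

`spde` estimates a univariate probability density from data by modelling its
logarithm in flexible exponential families. It is aimed at anyone who needs
smooth, boundary-bias-free density estimates with a defensible complexity
choice — e.g. for epidemiological or climatological samples where the number
of modes and bumps of the distribution carries scientific meaning and kernel
estimators either oversmooth or sprout spurious wiggles.

## The model

The density of the (linearly rescaled) data is

```
p(y | α) = exp[ U(y | α) − A(α) ],   U(y | α) = ψ(y) + Σ_j α_j φ_j(y),
```

an exponential family with canonical parameters α, sufficient statistics
φ_1..φ_J and log-partition function A(α) = log ∫ exp U. The basis functions
are polynomials, C² cubic splines (equidistant or quantile knots) or
trigonometric functions, optionally augmented with logarithmic or rational
boundary terms such as `log(y+1)` or `log y` that absorb power-law decay or
integrable singularities of the density at a domain endpoint. Supports may
be bounded `[a, b]`, the real line, or semi-infinite `[a, ∞)`; on unbounded
domains every basis function is continued linearly beyond the extreme data
points, which yields closed-form exponential tails under the strict slope
conditions `U'(y_a) > 0`, `U'(y_b) < 0`.

Before fitting, the basis is made *statistically orthogonal*: mean-centred
and orthonormalised under the empirical scalar product
`(e1, e2) = N⁻¹ Σ_n e1(y_n) e2(y_n)`, so the likelihood machinery collapses
to `l = −N log Z`, the likelihood equations to `m(α̂) = 0` (population means
of the statistics equal their sample means — an extended method of
moments), and the Fisher information to approximately `N · I`. The strictly
concave log-likelihood is maximised by a condition-capped Newton method with
slope-constrained backtracking. Model complexity — basis family, size,
boundary-term subset and spline knots (with minimum-occupancy pruning and
greedy knot deletion) — is selected by the Bayesian information criterion
`BIC = J log N − 2 l(α̂)`; the overall minimum-BIC model is the
semiparametric density estimate (SPDE).

## A worked example

```r
library(spde)
set.seed(1)
x <- faithful$eruptions                   # 272 Old Faithful durations
est <- spde(x, spde_domain("semi_infinite", a = 0),
            boundary_sets = list(character(0), "log", c("log", "recip")))
est
#> Semiparametric density estimate (min-BIC model)
#>   family: POL   J = 4 (boundary 2 + bulk 2)
#>   boundary terms: log, recip
#>   BIC (data scale): 544.03   log-likelihood: -260.81
#>   candidates evaluated: 98 (68 converged)
count_modes_bumps(est, c(1.25, 5.5))
#> modes bumps
#>     2     2
```

The selected model has potential `U(y) = α₁ log y + α₂/y + α₃ y + α₄ y²` — a
generalised inverse Gaussian density with a quadratic term generating the
bimodality; both eruption regimes appear as modes, with no boundary
artefact at zero duration. `predict(est, x0)` evaluates the density,
`write_density_grid(est, "density.tsv")` exports it, and

```r
u <- block_inflated_covariance(est$fit)        # C = J⁻¹ V J⁻¹
ens <- parameter_ensemble(est$fit, C = u$C, M = 1000, seed = 42)
```

propagates parameter uncertainty into an ensemble of densities (block
lengths > 1 inflate the covariance for serially dependent data;
`bootstrap_models()` is the resampling alternative).

The built-in benchmark reproduces the simulation studies on fifteen normal,
beta and gamma mixture test densities:

```r
run_simulation_study(7, N = 5000, n_reps = 20, estimator = "SPDE",
                     interval = c(-4, 4), seed = 1)
#> Simulation study: case 7, N = 5000, 20 replicates, estimator SPDE
#>   MISE x 1e4: 4.56   (failures: 0)
#>   correct modes: 20/20   correct bumps: 20/20 on [-4, 4] (truth 2/2)
#>   chosen families: SPL1:20
```

A thin shell front end is installed as `exec/spde`
(`spde fit --input sample.csv --domain bounded --a 0 --b 1 ...`).

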
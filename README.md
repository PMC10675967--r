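# hosplasso

LASSO variable selection for patient-level outcomes nested within hospitals.

## The problem

Administrative hospital data are clustered: patients sit inside hospitals,
and outcomes such as length of stay or in-hospital mortality differ
systematically between hospitals. When selecting a sparse set of
patient-level predictors (comorbidity indicators, age, admission type) from
a larger pool, ignoring this structure hurts twice:

* predictions lose the stable hospital-level part of the signal, and
* variables whose *prevalence* varies across hospitals (planned admission is
  the classic case) act as proxies for hospital effects and get selected with
  high apparent importance even when they have no within-hospital
  association with the outcome — the ecological fallacy.

`hosplasso` implements and compares three LASSO variants on such data:

| variant        | hospital handling                                      |
|----------------|--------------------------------------------------------|
| `no_hosps`     | hospitals ignored (pooled LASSO)                       |
| `hosps_fixed`  | hospitals as penalized reference-coded dummy variables |
| `hosps_random` | L1-penalized random-intercept model (penalized GLMM)   |

All three minimize a `1/n`-scaled penalized negative log-likelihood

```
(1/2n) Σᵢ wᵢ (zᵢ − β₀ − xᵢ'β)²  +  λ Σⱼ pⱼ ( α|βⱼ| + (1−α)/2 βⱼ² )
```

(identity link, or IRLS working response for the logit link), with an
unpenalized intercept. The `hosps_random` variant adds hospital intercepts
`b_h ~ N(0, τ²)` and fits by alternating an exact cluster-whitened
coordinate-descent step for `(β₀, β, b)` with an EM update of `(τ², φ²)`;
for the gaussian family this reaches the exact marginal maximum likelihood,
for the binomial family it is a PQL-type approximation. The coordinate
descent itself is the package's own compiled implementation; `glmnet` and
`lme4` appear only as cross-checking oracles in the test suite.

Around the estimators the package ships the full study machinery: a
synthetic clustered-data generator (including a structurally confounded
planned-admission scenario), the preprocessing rules (log-transform,
zero-variance and pairwise-correlation filters, per-split unit-variance
scaling), a certified 100-value penalty grid, tuning by cross-validation
(λ_min, λ_1se) or AIC/BIC with optional post-LASSO (relaxed) refits, a
hospital-coverage-constrained 20-fold sub-sampling evaluation (RMSE, AUC,
AUPRC, Brier score, predictive Bernoulli likelihood), and a top-5
stability-based variable-importance statistic. See the package vignette for
the full methods description.

## Worked example

Simulate a clustered dataset with five true predictors and a hospital-level
standard deviation of 0.5, preprocess it, and fit the random-intercept LASSO
tuned by BIC:

```r
library(hosplasso)

cfg <- scenario_config(
  n_hospitals = 25, hospital_size_range = c(30, 60),
  n_comorbidity_vars = 10,
  beta_true = c(planned_admission = 0.2, age = 0.005,
                setNames(c(rep(0.4, 3), rep(0, 7)), sprintf("comorb_%02d", 1:10))),
  tau = 0.5, noise_sd = 0.6, seed = 42
)
dataset <- simulate_hospital_data(cfg)
dataset
#> <hl_dataset> 1089 patients, 12 predictors, 25 hospitals, family = gaussian

prep <- preprocess_global(dataset)                # log-transform + filters
d    <- scale_unit_variance(prep$data)$train      # unit-variance predictors

grid <- build_lambda_grid(d, "hosps_random")
grid
#> <hl_lambda_grid> 100 values, 0.2056 .. 0.0002056 (log-linear, variant hosps_random); null at top, 3 selected at value 5

tuned <- tune_ic(d, grid, "hosps_random", criterion = "bic")
tuned
#> <hl_tuning> hosps_random / bic: chosen lambda = 0.02535, 5 variable(s) selected

dplyr::filter(tidy(tuned$chosen_fit), estimate != 0)
#> # A tibble: 6 × 3
#>   term              estimate term_type
#>   <chr>                <dbl> <chr>
#> 1 (Intercept)         1.96   intercept
#> 2 planned_admission   0.0845 fixed
#> 3 age                 0.0843 fixed
#> 4 comorb_01           0.172  fixed
#> 5 comorb_02           0.179  fixed
#> 6 comorb_03           0.140  fixed

tuned$chosen_fit$tau
#> [1] 0.5862008
```

Exactly the five truly nonzero predictors are selected, and the estimated
hospital-level standard deviation (0.59) is close to the generating value
(0.5). The full sub-sampling comparison of the variants:

```r
splits <- make_subsamples(prep$data, R = 10L, seed = 43)
ex <- run_experiment(prep$data, splits,
  variants = c("no_hosps", "hosps_fixed", "hosps_random"),
  criteria = "cv_min", cv_seed = 44)

glance(ex)
#> # A tibble: 3 × 7
#>   variant      criterion metric  mean     se     sd     n
#>   <chr>        <chr>     <chr>  <dbl>  <dbl>  <dbl> <int>
#> 1 hosps_fixed  cv_min    rmse   0.609 0.0138 0.0435    10
#> 2 hosps_random cv_min    rmse   0.609 0.0141 0.0446    10
#> 3 no_hosps     cv_min    rmse   0.805 0.0232 0.0734    10

dplyr::arrange(dplyr::filter(ex$importance, variant == "hosps_random"),
               dplyr::desc(top_rate)) |> head(6)
#> # A tibble: 6 × 6
#>   variant      variable          top_rate mean_coef n_top label
#>   <chr>        <chr>                <dbl>     <dbl> <int> <chr>
#> 1 hosps_random comorb_02                1    0.193     10 100% (.19)
#> 2 hosps_random comorb_01                1    0.186     10 100% (.19)
#> 3 hosps_random comorb_03                1    0.151     10 100% (.15)
#> 4 hosps_random planned_admission        1    0.111     10 100% (.11)
#> 5 hosps_random age                      1    0.0987    10 100% (.10)
#> 6 hosps_random comorb_04                0   NA          0 0% (-)
```

Both hospital-aware variants beat the pooled LASSO by about 25% in held-out
RMSE, and the five true signals are in the importance top five in every
replicate. `run_pipeline()` wraps the whole sequence — simulate (or read),
preprocess, split, tune, score — and writes deterministic CSV/JSON artifacts
from a single configuration object.

## License

MIT. See `LICENSE`.
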
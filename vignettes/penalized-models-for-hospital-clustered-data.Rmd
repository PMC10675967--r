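---
title: "Penalized models for hospital-clustered data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized models for hospital-clustered data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

```{r load}
library(hosplasso)
```

# The problem

Routinely collected hospital data have a two-level structure: patients are
nested within hospitals, and outcomes such as length of stay or in-hospital
mortality vary systematically *between* hospitals as well as between
patients. When the goal is to select a sparse set of patient-level predictors
(comorbidity indicators, age, admission type) from a larger candidate pool,
ignoring the hospital level is dangerous twice over:

1. **Predictive loss.** A model without hospital effects cannot use the
   stable part of a hospital's deviation from the average, so its test-set
   predictions for patients in systematically high- or low-outcome hospitals
   are biased.
2. **Ecological confounding.** A patient-level variable whose *prevalence*
   differs across hospitals can act as a proxy for the hospital effect. A
   pooled analysis may then select it with high apparent importance even when
   it has no within-hospital association with the outcome — an instance of
   the ecological fallacy. Planned (elective) admission is the canonical
   example: some hospitals admit almost exclusively electively, others not at
   all.

The package implements and compares three LASSO variants on such data:

* `no_hosps` — the plain LASSO, hospitals ignored;
* `hosps_fixed` — hospitals as reference-coded dummy variables, penalized
  like any other predictor;
* `hosps_random` — an L1-penalized random-intercept model
  (a penalized GLMM).

# The models

All three variants minimize a penalized, `1/n`-scaled negative
log-likelihood. For the fixed-effects variants with response $z_i$
(identity link) or working response (logit link),

$$
\frac{1}{2n}\sum_i w_i\,(z_i - \beta_0 - x_i^\top\beta)^2
 + \lambda \sum_j p_j\Big(\alpha\,|\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2\Big),
$$

with unpenalized intercept ($p_0 = 0$), penalty factors $p_j \in \{0, 1\}$,
and elastic-net mixing $\alpha$ ($\alpha = 1$ is the LASSO; the "near-LASSO"
$\alpha = 0.99999$ is provided because some penalized-regression software
only exposes the elastic net — the two are numerically indistinguishable,
which the test suite asserts). Optimization is cyclic coordinate descent with
soft-thresholding in compiled code; the binomial family wraps it in an
iteratively reweighted least-squares loop with working weights floored at
$10^{-5}$.

The `hosps_random` variant adds a hospital intercept
$b_h \sim N(0, \tau^2)$:

$$
y_{hi} = \beta_0 + x_{hi}^\top\beta + b_h + \varepsilon_{hi}
\qquad\text{or}\qquad
\mathrm{logit}\,P(y_{hi}=1) = \beta_0 + x_{hi}^\top\beta + b_h ,
$$

with only $\beta$ penalized. Fitting alternates two exact blocks at the
current variance components: the random intercepts are profiled out of the
working least-squares problem by a per-hospital whitening transform
(subtract $c_h$ times the weighted cluster sum from every row, with
$c_h = (1 - 1/\sqrt{1 + (\tau^2/\phi^2)\,sw_h})/sw_h$ and $sw_h$ the
hospital's working-weight sum), so a single coordinate-descent call solves
the joint $(\beta_0, \beta, b)$ problem; then an $O(H)$ EM step updates
$(b, \tau^2, \phi^2)$, adding the conditional variance of each $b_h$ to its
squared prediction so the variance estimate does not collapse from shrinkage
alone. For the gaussian family this converges to the exact marginal maximum
likelihood (verified against `lme4::lmer(REML = FALSE)` to machine
precision at $\lambda = 0$); for the binomial family it is a PQL-type
approximation whose reported log-likelihood uses a Laplace correction.
$\hat\tau = 0$ is a valid boundary solution and is reported, not raised.

## Assumptions

* Two-level nesting only (patients in hospitals); no crossed effects or
  random slopes.
* Random intercepts are normal on the link scale with a common $\tau$.
* The continuous outcome is positive and modelled linearly on the log scale;
  all gaussian-family predictions and errors live on that scale.
* Predictors carry no missing values; binary predictors are coded 0/1.

# Tuning

`build_lambda_grid()` constructs exactly 100 log-linearly spaced descending
penalties. The top of the grid is the KKT bound
$\max_j |x_j^\top r_0|/n$ on the null-model residual (intercept only;
intercept plus predicted random intercepts for `hosps_random`), inflated by
a 1.05 safety factor; the bottom is `ratio` ($10^{-3}$, halved with bounded
retries) times the top. Two rules are *certified by fitting*: the first
value yields the null model and the fifth already selects at least one
variable. The grid therefore always has a strictly positive lower endpoint;
the unpenalized fit is available separately via $\lambda = 0$.

Four selection criteria are available:

* `cv_min` / `cv_1se` — internal cross-validation of the held-out deviance
  (MSE on the log scale, or $-2\times$ mean Bernoulli log-likelihood), with
  the usual minimizer and one-standard-error choices; ties go to the larger
  penalty. Fixed-effects variants use 10 plain row-wise folds; the
  random-effects variant uses 5 cluster-aware folds (round-robin within each
  hospital, single-patient hospitals pinned to the training side) so every
  fold's training part covers every hospital. `cv_1se` is computed for the
  random variant only on request, mirroring the tooling asymmetry common in
  this literature.
* `aic` / `bic` — information criteria on the full-data path, with
  `df = 1 + #nonzero` for the fixed variants and
  `df = #nonzero + intercept + τ (+ φ)` for the mixed model. These df
  conventions are declared choices: the standard LASSO df estimator for the
  fixed variants, and the analogous count for the mixed model, where no
  standard exists.

`estimator = "post"` tunes on post-LASSO (relaxed) refits: the selected
active set is refitted without penalty (unpenalized mixed ML for
`hosps_random`), zeros preserved elsewhere.

# Evaluation design

`make_subsamples()` draws `R = 20` train/test replicates with
`|test| = round(n/20)`, repaired so every hospital present in a test set
keeps at least one training row (move one test row of an uncovered hospital
back, redraw a replacement from hospitals with at least two training rows).
Test sets may overlap across replicates. The same splits — verified by
checksums in every report — are consumed by all variants.

Per replicate, `run_experiment()` re-applies the split-level preparation
(zero-variance removal on the training part, unit-variance scaling with
training SDs applied to both parts), builds the grid, tunes every variant
under every criterion, predicts the test part, and scores: RMSE on the log
scale (gaussian) or AUC, AUPRC, Brier score and mean predictive Bernoulli
likelihood (binomial, probabilities clipped to $[10^{-12}, 1-10^{-12}]$).
Aggregates report means with both SE ($\mathrm{SD}/\sqrt{R}$, the table
convention) and SD (the figure convention). Binomial mixed-model predictions
are *conditional* on the predicted hospital intercept (link-scale $\hat b_h$),
not marginalized over it — a declared choice.

Variable importance follows the stability-selection idea: per replicate, the
five variables with the largest absolute standardized coefficients in the
CV-selected (`cv_min`) model; a variable's importance is the share of
replicates in which it made that top five, reported as e.g. `100% (.16)`
(rate, mean coefficient). Ties at the cut break by variable order;
replicates with fewer than five nonzero coefficients contribute all of them
and the shortfall is recorded.

# Data preparation

`preprocess_global()` applies, in order: keep positive outcomes and
log-transform (gaussian only), drop zero-variance predictors, and drop one
member of every predictor pair with $|r| > 0.95$ — the member with the
smaller absolute correlation with the outcome. The pair order is
deterministic (descending $|r|$, ties by column order) and, by default,
offending pairs are re-examined after every removal; a single-pass variant
is exposed as `iterative = FALSE` because either reading of "remove one of
each highly correlated pair" is defensible. Scaling is deliberately *not*
global: it is recomputed per training split. Scaling divides by the training
SD without mean-centering (the intercept absorbs means); `center = TRUE` is
available.

# The synthetic generator

`simulate_hospital_data()` draws from the two-level model the estimators
assume, structured like national hospital administrative data: hospital
sizes uniform on an integer range; hospital intercepts $N(0, \tau^2)$; a
planned-admission indicator whose hospital prevalence is structurally
confounded (by default 14.5% of hospitals all-zero, 22.5% all-one, the rest
uniform on 0.1–0.9, so the variable has both within- and between-hospital
variance); age uniform on 18–95; a block of Elixhauser-style binary
comorbidity indicators with per-variable prevalence. The gaussian-log family
emits the *raw* positive outcome $y = \exp(\eta + N(0, \sigma^2))$ so that
preprocessing exercises the log-transform; the binomial family draws
$y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}\eta)$ with a 4% default base
rate. One global RNG stream draws hospital-level quantities and seeds one
sub-stream per hospital, making generation bit-reproducible and a hospital's
patients independent of hospital order.

The default $\tau = 0.3$ with log-scale noise 0.8 gives an intra-class
correlation of about 0.12 — hospital-level variation visible but a minority
share, a deliberate calibration since administrative reports rarely publish
outcome ICCs (plausible range 0.05–0.2).

`simulate_confounded_data()` modifies one thing: the planned-admission
coefficient is forced to zero and each hospital's intercept is shifted by
`between_effect` times its planned-admission prevalence. The variable is
then a *purely ecological* proxy — exactly the situation in which a pooled
LASSO should select it and a random-intercept LASSO should not.

The generator's scope is deliberately structural: it emulates cluster sizes,
confounding patterns, outcome skewness and rare binary outcomes, not
diagnosis coding systems or case definitions.

# A worked example

A small end-to-end comparison (sizes here are chosen for a fast vignette;
the package's own studies use 40–60 hospitals of 20–100 patients, around
2,000–4,000 patients — desk-scale stand-ins for national data):

```{r example}
cfg <- scenario_config(
  n_hospitals = 15, hospital_size_range = c(15, 25),
  n_comorbidity_vars = 8, tau = 0.5, seed = 42
)
dataset <- simulate_hospital_data(cfg)
dataset

prep <- preprocess_global(dataset)
splits <- make_subsamples(prep$data, R = 5L, seed = 43)
experiment <- run_experiment(
  prep$data, splits,
  variants = c("no_hosps", "hosps_random"),
  criteria = c("cv_min", "bic"), cv_seed = 44
)
glance(experiment)
```

The random-intercept variant's RMSE advantage grows with $\tau$; at
$\tau = 0$ the variants coincide up to selection noise.

```{r paths}
d_std <- scale_unit_variance(prep$data)$train
grid <- build_lambda_grid(d_std, "no_hosps")
autoplot(fit_lasso_path(d_std, grid), highlight = "planned_admission")
```

```{r tuning-curve}
autoplot(tune_ic(d_std, grid, "no_hosps", criterion = "bic"))
```

# Numerical choices

* Coordinate-descent tolerance $10^{-7}$ on the largest coefficient update
  per sweep, $10^5$ sweep budget; IRLS outer tolerance $10^{-8}$ on the
  deviance; mixed-model outer tolerance $10^{-6}$ on the largest parameter
  change, 500 outer iterations.
* The mixed model's variance components are updated by an EM-type moment
  step with shrinkage correction by default;
  `variance_update = "profile"` switches to a direct profile-likelihood
  line search over the variance ratio. Both target the same stationary
  equations and agree at convergence (asserted in the test suite).
* The intercept is never penalized; hospital dummies in `hosps_fixed` are
  penalized by default (`penalize_dummies = FALSE` exempts them) — whether
  to exempt them is a genuinely open modelling question, so both are
  offered.
* Reference coding drops the first hospital in sorted label order.
* A separable binomial problem at $\lambda = 0$ (no finite MLE) raises an
  error rather than returning a diverging fit.
* $\hat\tau^2 < 10^{-8}$ is truncated to the $\tau = 0$ boundary.

# Reproducibility

Every stochastic step takes an explicit seed (`run_config()` expands one
top-level seed into data, split, and CV seeds deterministically), and two
runs of `run_pipeline()` with the same configuration produce bit-identical
CSV artifacts. `scripts/acceptance.R` in the source tree runs the headline
analysis end to end:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

# Limitations

* The binomial mixed model is a PQL-type estimator; its $\hat\tau$ carries
  the well-known mild attenuation relative to adaptive-quadrature ML, and
  its AIC/BIC rest on a Laplace-approximate likelihood.
* Degrees of freedom for the information criteria are counting conventions,
  not exact risk estimates; for the mixed model no standard convention
  exists.
* Only random intercepts are supported — no random slopes, crossed designs,
  or deeper nesting.
* The importance statistic quantifies selection stability under
  sub-sampling, not effect size or statistical significance.
* Synthetic scenarios are structural stand-ins; none of the shipped defaults
  claims to reproduce any particular health system's numbers.
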
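---
title: "Modeling and validating individual eGFR trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and validating individual eGFR trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chronic kidney disease (CKD) in type 2 diabetes progresses at very
different rates across individuals. Kidney function is monitored through
the estimated glomerular filtration rate (eGFR, mL/min/1.73 m², computed
from serum creatinine, age and sex with the race-free CKD-EPI 2021
equation; see `ckd_epi_2021()`). A clinically useful tool predicts a
patient's *future* eGFR values — and the probability that they are a
rapid progressor — from variables available at a single routine care
visit.

`egfrtraj` implements such a tool end to end: a linear mixed-effects
trajectory model in which the baseline eGFR is part of the outcome
vector, empirical-Bayes updating of an individual's random effects from
that single baseline measurement, per-individual slope distributions and
rapid-progression probabilities, and leave-one-country-out validation
with cluster-bootstrap confidence intervals. Because the underlying
multi-cohort patient data are not public, the package ships a synthetic
cohort generator with the same statistical structure, so every step is
testable.

# The model

For subject $i$ in country $c(i)$, the eGFR measured at time $t_{ij}$
(years since baseline, $t_{i1} = 0$) is modeled as

$$
y_{ij} = x_i^\top\beta + \beta_t\, t_{ij} + (x_i t_{ij})^\top\gamma
  + u_{c(i)} + b_{0i} + b_{1i}\, t_{ij} + \varepsilon_{ij},
$$

where

* $x_i$ are 12 baseline predictors: age, sex, BMI, ever-smoking, HbA1c,
  hemoglobin, serum cholesterol, mean arterial pressure, log2-transformed
  urinary albumin–creatinine ratio (UACR; the log2 tames its heavy right
  tail), and indicators for glucose-, blood-pressure- and lipid-lowering
  medication (`egfr_predictors()`);
* every predictor also interacts with time ($\gamma$), so covariates can
  shift the *slope* of decline, not just the level;
* $u_c \sim N(0, \tau^2)$ is a country-level random intercept — the
  individual intercepts are nested within countries, which also absorbs
  systematic differences between cohorts such as creatinine assay
  offsets;
* $(b_{0i}, b_{1i}) \sim N(0, G)$ are the individual random intercept and
  slope with unstructured $2\times 2$ covariance $G$;
* $\varepsilon_{ij} \sim N(0, \sigma^2)$ is measurement noise.

The fixed-effect dimension at defaults is $1 + 12 + 1 + 12 = 26$.
Baseline eGFR is deliberately **not** a covariate: it is the first
element of the outcome vector. Baseline measurements carry the same
noise as follow-up measurements; putting them in the outcome lets the
model estimate that noise instead of conditioning on it as if exact.

## Fitting

`fit_egfr_lmm()` maximizes the restricted likelihood (REML by default;
ML is available via `egfr_model_spec(method = "ML")`). The implementation
profiles $\beta$ and $\sigma^2$ out of the criterion and optimizes over
the Cholesky factor of the relative covariance $G/\sigma^2$ plus the
relative country standard deviation $\tau/\sigma$ — four parameters. The
Cholesky parameterization enforces positive semi-definiteness, and
boundary (singular) fits are legal, so cohorts truly generated with
$G = 0$ come back with $\hat G \approx 0$ rather than an error.

Each criterion evaluation solves one sparse penalized least-squares
problem (sparse Cholesky via the Matrix package; the random-effect
design has two columns per subject plus one per country). Optimization
runs L-BFGS-B under the boundary constraints with a Nelder–Mead polish
(relative tolerance $10^{-13}$) and one perturbed restart on failure;
`converged = FALSE` is returned rather than an error if the optimizer
stalls. In the test suite this reproduces an independent general-purpose
mixed-model implementation to $|\Delta \log L| < 10^{-4}$ and relative
parameter error $< 10^{-3}$.

Rank-deficient fixed-effect designs fail loudly, naming the collinear
columns; subjects with missing predictors are dropped (complete-case
policy) with a reported count.

## Variance explained

`r2_nakagawa()` decomposes the visit-level variance into the
fixed-effect part $\operatorname{var}(X\hat\beta)$, the random part
$\overline{z^\top \hat G z} + \hat\tau^2$ (the random-slope contribution
averaged over the observed design, $z = (1, t)$), and $\hat\sigma^2$.
Marginal R² uses the fixed part only; conditional R² adds the random
part. With sizable individual heterogeneity the conditional value is far
above the marginal one — on the default synthetic cohorts roughly 0.9
versus 0.2.

`drop_one_marginal_r2()` measures predictor importance as the decrease
in marginal R² after refitting without a predictor (main effect and time
interaction together). Both fits' fixed-effect variances are referenced
to the *full* model's variance budget; with each model's own denominator
the difference can be slightly negative for null predictors because the
variance components shift, which would make importances incomparable.

`standardized_coefficients()` reports continuous coefficients per 1 SD
of the predictor (training-sample SDs) and binary coefficients on their
natural 0/1 scale, the convention that makes main effects comparable in
a coefficient plot.

# Predicting a new individual

## Empirical-Bayes updating from one baseline eGFR

A new individual arrives with covariates $x$ and a single baseline eGFR
$y_0$. Writing $r = y_0 - x_0^\top\hat\beta - \hat u_{c}$ for the
baseline residual and $z = (1, 0)$,

$$
\mathbb{E}[b \mid y_0] = G z\,(z^\top G z + s^2)^{-1} r, \qquad
\operatorname{cov}[b \mid y_0] = G - G z\,(z^\top G z + s^2)^{-1} z^\top G,
$$

with $s^2 = \sigma^2$ for a training country (whose posterior mean
effect $\hat u_c$ is used) and $s^2 = \sigma^2 + \tau^2$ with
$\hat u_c = 0$ for an unseen country. This is plain Gaussian
conditioning (`update_random_effects()`, checked against a brute-force
joint-normal oracle to $10^{-8}$). Only the baseline measurement is
used; later measurements are not folded in dynamically — the tool is
meant for the first visit.

Conditioning never inflates the posterior variances, and the intercept
update never exceeds the shrinkage bound
$|r|\,G_{11}/(G_{11}+\sigma^2)$.

## Trajectories, slopes, risk

`predict_trajectory()` evaluates
$\hat y(t) = x(t)^\top\hat\beta + \hat u_c + \hat b_0 + \hat b_1 t$ with
predictive variance $(1,t)\,\mathrm{cov}[b\mid y_0]\,(1,t)^\top +
\sigma^2$ (plus $\tau^2$ for unseen countries, plus optionally the
fixed-effect estimation term $x(t)^\top \widehat{\mathrm{cov}}(\hat\beta)\,
x(t)$). Predictions beyond 5 years are flagged and warned about, not
refused: follow-up data thin out with horizon, so the model is
considered reliable only within 5 years.

The individual slope is the time derivative of the trajectory:
$\hat\beta_t + x^\top\hat\gamma + \hat b_1$, with variance equal to the
posterior random-slope variance (`slope_distribution()`). Adding the
fixed-effect estimation uncertainty of the time block is an opt-in flag
(`include_beta_uncertainty`); the default excludes it so that the
reported spread reflects individual heterogeneity, and both variants are
available because either convention is defensible.

The probability of rapid progression is the predictive normal CDF at the
threshold $-3$ mL/min/1.73 m² per year:
$\Phi\!\big((-3 - \hat m)/\hat s\big)$ (`prob_rapid_progression()`, the
threshold is a parameter). On well-specified simulations the mean
predicted probability matches the realized fraction of true slopes below
$-3$ to within a few percentage points (calibration-in-the-large).

# Validation design

`internal_external_cv()` performs internal–external cross-validation
with country as the non-random splitting unit: each country is held out
in turn, the model is refit on the remainder, and every held-out subject
is predicted *after* empirical-Bayes updating from their baseline eGFR.
Held-out pairs from all splits are pooled (one cross-validated row per
follow-up year, rather than per-split averages) and summarized per year:

* a visit at time $t$ belongs to follow-up year $y$ when
  $t \in (y - 0.5,\, y + 0.5]$; baseline is excluded;
* **predicted R²** $= 1 - \sum(o - p)^2 / \sum(o - \bar o)^2$, which can
  go negative for worse-than-mean predictions;
* **C statistic**: the probability, over subject pairs with unequal
  observed values, that the prediction ordering agrees with the observed
  ordering, ties in predictions counting ½ (a small compiled kernel;
  verified against exhaustive enumeration). It is invariant to strictly
  increasing transforms of the predictions;
* **calibration slope**: OLS slope of observed on predicted, 1 being
  ideal.

Confidence intervals are percentile bootstrap over **subjects** (not
rows), respecting within-subject correlation; 1000 resamples by default
(200 in the heavier test scenarios). Year cells with no visits are
reported as missing, not zero — e.g. an external cohort without year-1
visits yields an NA row for year 1. `external_validate()` applies the
same battery to a frozen model on a new cohort, and `plot_calibration()`
draws observed-versus-predicted panels before and after updating with
the 45° identity line, later years lighter.

On well-specified simulations the predicted R² and C statistic decrease
with follow-up year — individual slope heterogeneity compounds with
horizon — while the per-year calibration slope stays near 1. This
decaying-discrimination / stable-calibration pattern is the qualitative
signature the acceptance suite asserts.

# The synthetic cohort generator

`simulate_cohort()` draws cohorts with exactly the generating structure
the model assumes, plus the operational quirks of multi-cohort studies:

* **three cohort archetypes** (configurable): a biennial-visit cohort
  with low baseline eGFR (target mean 52.4), a yearly-visit cohort
  (89.6), and a cohort with no year-1 visit (81.2). Nominal visit times
  get Gaussian jitter (SD 0.1 years — no within-subject irregularity
  statistics were available to calibrate this, so it is a free default)
  and per-visit missing-completely-at-random dropout (default 5%);
* **covariates** drawn independently per predictor from laws calibrated
  to the published cohort descriptives (`default_covariate_table()`);
  age is truncated to 18–75 years, and log2-UACR is generated normal so
  UACR is log-normal-like. Independence is adequate here because no
  material pairwise correlations were reported for these predictors;
* **truth record**: realized $(b_{0i}, b_{1i})$, country effects and
  true slopes are emitted alongside the data for recovery tests, and are
  never consumed by fitting code;
* **inclusion filters** (`apply_inclusion_filters()`): at least 3 eGFR
  readings, at least 2 years of follow-up, baseline eGFR ≥ 30; exclusion
  counts are reported per criterion, and subjects can fail several at
  once.

Generating values chosen once (clinically plausible, documented here so
they are not mistaken for estimates): time main effect $-0.5$/yr with
interaction effects such that the implied mean slope is about $-1.4$
mL/min/1.73 m² per year, matching the reported median declines;
$G = \begin{pmatrix} 144 & -4 \\ -4 & 4\end{pmatrix}$ (intercept SD 12,
slope SD 2/yr — the slope IQR then spans roughly $-3.5$ to $-0.2$);
$\tau^2 = 9$ (country SD 3, the scale of assay-level offsets);
$\sigma^2 = 16$ (measurement SD 4). Age is the dominant predictor
($-0.45$ per year).

Two standard configurations matter:

* `sim_config()` (default): country intercept *offsets* are solved
  analytically so the expected baseline eGFR means equal the cohort
  targets 52.4 / 89.6 / 81.2. Use it to emulate cohort descriptives.
  Note that leave-one-country-out validation under this configuration is
  intentionally hard: fixed offsets of tens of mL are not exchangeable
  draws from $N(0, \tau^2)$, the fitted $\tau^2$ explodes, and updating
  under-corrects — an honest picture of transporting a model to a
  systematically different cohort.
* `sim_config(target_baseline_egfr = NULL)`: no fixed offsets; country
  heterogeneity comes only from $u_c \sim N(0, \tau^2)$. This is the
  *well-specified* configuration used for parameter-recovery, risk
  calibration and validation-pattern checks.

What the generator does **not** emulate — hence what passing tests do
not show about real data: correlated covariates, informative (illness-
driven) dropout, assay drift over time, non-linear trajectories,
medication changes after baseline, and treatment effects of drugs that
entered practice after the emulated recruitment era. Simulated serum
creatinine is also out of scope; the generator emits eGFR directly
(`ckd_epi_2021()` is provided for working from creatinine).

# Numerical choices and conventions

* REML is the default criterion (ML available for likelihood-ratio
  work); the country term is implemented as a scalar variance component
  on the country indicator design, equivalent to nesting individual
  intercepts within countries, with country effects recovered as
  posterior means after the fit.
* Predictors enter unstandardized except log2(UACR); standardization is
  reporting-only, because the coefficient-plot convention mixes
  standardized continuous and raw binary terms.
* Time origin is the baseline visit; time is in years.
* Optimizer: L-BFGS-B (`factr = 1e3`, `pgtol = 1e-8`) + Nelder–Mead
  polish (`reltol = 1e-13`), one perturbed restart; non-finite
  criteria are fenced to a large value so the optimizer retreats.
* C-statistic ties: ½ credit for tied predictions; pairs with tied
  observations are excluded from the denominator.
* Undefined metrics (zero observed variance, all-tied observations,
  zero prediction variance, < 2–3 pairs) are `NA`, never 0.
* Bootstrap CIs are percentile-based; with `n_boot = 1` both bounds
  collapse onto the single resample.
* All randomness flows from explicit integer seeds: the generator's
  seed lives in its config, validation takes a `seed` argument, and
  `run_pipeline()` derives stage seeds from one master seed, recorded in
  every provenance sidecar.

Problem sizes in the shipped test suite were chosen to exercise the
asymptotics while keeping a full run within a few minutes on one core:
unit fixtures of 30–450 subjects, recovery and risk calibration at ~2100
subjects with yearly visits, and the validation-pattern scenario at
3000 subjects with 200 bootstrap resamples.

# Limitations

The model is linear in time per individual; genuinely non-linear decline
(e.g. late acceleration) is captured only through the noise and slope
distribution. The deployed coefficient values from the original
multi-cohort analysis are not embedded — the published appendix with the
unstandardized coefficients was not available — so the package
reproduces the *procedure* and must be fit to data (real or synthetic)
before prediction. Decision-analytic evaluation (net benefit, impact on
care) is out of scope.
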
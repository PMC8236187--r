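---
title: "Methods: building and applying development-stage methylation clocks"
author: "devclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and applying development-stage methylation clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devclock)
```

## The problem

Epigenetic clocks predict age from DNA methylation levels at a sparse set
of CpG probes. Clocks trained on postnatal tissue extrapolate poorly into
prenatal development, where methylation changes rapidly: a clock
calibrated on the days-post-conception (dpc) timescale is needed to place
fetal brain samples — and stem-cell models of neuronal differentiation —
on a developmental axis. `devclock` implements the full workflow: array
QC and normalization, harmonization of heterogeneous age encodings to
dpc, penalized training of a clock, application of arbitrary published
coefficient sets, accuracy evaluation, and the group statistics used to
compare cellular differentiation stages.

## The model

Training regresses chronological age $y_i$ (dpc) on the beta values
$x_{ij} \in [0,1]$ of all available probes with the elastic net:

$$\min_{\beta_0, \beta} \frac{1}{2n}\sum_i\big(y_i - \beta_0 -
x_i^\top\beta\big)^2 + \lambda\Big[\alpha\|\beta\|_1 +
\tfrac{1-\alpha}{2}\|\beta\|_2^2\Big]$$

with mixing $\alpha = 0.5$ by default and $\lambda$ selected by ten-fold
cross-validation. The L1 term gives a sparse, portable probe set; the L2
term stabilizes selection among the heavily correlated probes typical of
methylation arrays. Fitting is delegated to the coordinate-descent
solver in `glmnet` — the standard implementation for this model class —
behind `fit_elastic_net_clock()`; the package's own contribution is the
surrounding estimand: fold construction, penalty selection, coefficient
extraction onto the beta scale, and the clock object that travels with
its unit and transform metadata.

Two numerical conventions matter when cross-checking solutions:

* **Predictor standardization.** Predictors are standardized internally
  (population-variance convention) and coefficients are returned on the
  original beta scale. Stationarity (KKT) conditions therefore hold in
  the standardized coordinates, which is what `en_kkt_violation()`
  evaluates when `standardize = TRUE`.
* **Response scaling.** Gaussian coordinate-descent solvers rescale the
  response to unit variance before fitting and report $\lambda$ back on
  the original response scale. The L1 conditions are unaffected, but the
  ridge term acquires an effective weight $\lambda(1-\alpha)/s_y$, with
  $s_y$ the population standard deviation of the response.
  `en_kkt_violation()` accounts for this by default and exposes
  `response_sd = 1` for responses that were pre-standardized; the test
  suite checks the textbook ridge closed form on a unit-variance
  response and the solver convention on the raw dpc scale.

The $\lambda$ selection rule is CV-minimum by default, with the one-SE
rule available (`lambda_rule = "one_se"`); the published applications of
this model class do not always state which rule they used, so both are
exposed. The default grid is 100 log-spaced values from the data-derived
$\lambda_{max}$ down to $10^{-4}\lambda_{max}$. CV folds are built by
shuffling samples under the training seed and dealing them round-robin,
so refitting with the same seed reproduces the selected $\lambda$
exactly. The response is raw dpc — no age transform is applied before
regression; log-linear age transforms only enter when *applying* clocks
that were trained on transformed ages.

## Quality control and normalization

`pfilter()` applies the standard two-pass detection rule: a sample is
excluded iff **strictly more than** 1% of its probes have detection
p > 0.05, then a probe is excluded iff strictly more than 1% of the
*retained* samples fail it. The strict inequality mirrors the usual
"> 1%" phrasing, and the sample-then-probe order matches the common
reference behavior; both thresholds and the p cutoff are arguments. The
filter is idempotent, which the suite verifies.

`dasen_normalize()` implements probe-type-aware quantile normalization
of intensities: (1) Type II methylated and unmethylated intensities are
shifted per sample so their low-intensity background quantile (5th
percentile by default) matches Type I, with offsets smoothed by a linear
fit against sample index — the exact smoothing used by reference
implementations is under-documented, so this deliberately simple,
reproducible choice is exposed via `background_quantile` and `smooth`;
(2) M and U are quantile-normalized across samples separately within
each probe type (four independent normalizations, each setting every
sample's sorted values to the across-sample mean of order statistics,
ties averaged — the engine is `limma::normalizeQuantiles`); (3) betas
are `M / (M + U + 100)`, the standard offset. Intensities pushed
negative by the background shift are clamped at zero and counted.
`beta_quantile_normalize()` provides the within-type quantile step alone
for public datasets distributed without raw intensities.

The train/test split (`stratified_split()`) draws `floor(0.75 n + 0.5)`
training samples per dataset (round half up — deterministic and sensible
for small strata) uniformly at random under a seed. Blacklisted
(SNP-affected or cross-hybridizing) probes are removed against a
user-supplied annotation, since published blacklists are versioned
resources rather than package constants.

## Age harmonization

`to_dpc()` fixes birth at 280 dpc: years convert as
$y \times 365 + 280$ (negative years are prenatal), weeks
post-conception as $w \times 7$. Some pipeline descriptions state the
weeks conversion as a *division* by 7, which is dimensionally
inconsistent (14 gestational weeks is 98 days); the package multiplies,
and retains `strict_literal = TRUE` as an audit mode reproducing the
literal arithmetic. Developmental stages partition the axis at 63 dpc
(embryonic/fetal) and 280 dpc (fetal/postnatal). The log-linear
transform of adult clocks is inverted by `horvath_anti_transform()`
(knot at `adult_age = 20` years by default); its two branches meet at
score 0 and the prenatal limit is −1 year, i.e. conception.

## Applying clocks

`predict_age()` computes the linear predictor over the clock's probes,
back-transforms, and converts to dpc. Missing clock probes — the real
hazard when moving between 450K and EPIC platforms — are governed by an
explicit policy with `fail` as the default: silently dropping probes
changes the estimand. Predictions outside the training age range are
*flagged, never clipped*, because out-of-range behavior is itself a
diagnostic of clock applicability. Gestational-age clocks published on
the week scale carry `output_unit = "weeks_ga"` in their coefficient
files and convert as weeks × 7.

## Evaluation and group statistics

Accuracy is Pearson's r plus RMSE with a plain mean (no
degrees-of-freedom correction), and `range_restricted_accuracy()`
recomputes both below a chronological-age cutoff to separate
interpolation error from extrapolation error. The sex sensitivity
analysis is OLS of predicted age on age, sex and their interaction
(female reference, configurable), with Wald t-tests and optional sample
exclusions for outlier sensitivity refits.

Stage comparisons use Welch's t-test by default (the default of standard
software when variance equality is not asserted; pooled available),
one-way ANOVA with Tukey HSD (Tukey–Kramer standard errors for
unbalanced groups) when three stages are present, and, to pool across
studies, a linear mixed model with stage fixed effects (iPSC reference,
dummies for NPC and neuron) and a per-dataset random intercept, fitted
by REML. Fixed-effect p-values are Wald z; Satterthwaite-style
corrections would enlarge small-sample p-values, and with few datasets
that difference is material — the choice is documented rather than
hidden. A single dataset falls back to OLS with a warning.

## The synthetic generator

`simulate_age_dataset()` emulates the statistical structure the method
assumes: ages uniform on 37–185 dpc (a fetal training window whose upper
edge deliberately supports extrapolation experiments above it),
age-associated probes with linear logit-scale trajectories
($\mathrm{logit}\,\mu_j = a_j + s_j\,\mathrm{age}$, baselines uniform on
±1.5 logits, slopes ±`effect_scale`·U(0.5, 1.5)), Gaussian logit noise
(sd 0.02 by default), matched M/U intensities satisfying
$\beta = M/(M+U+100)$ exactly under lognormal depths, and detection
p-values with a configurable failure rate. Probe-level and sample-level
draws use separate seeds so probe truth can be held fixed across
replicates. Defaults are 200 samples × 2000 probes with 2.5% (50)
age probes.

What it does **not** emulate: probe-probe correlation blocks, dye bias
and bead-count artifacts, cell-composition heterogeneity, mQTL effects,
or batch structure. Passing tests therefore demonstrate correctness of
the estimator and pipeline mechanics under the assumed generative model,
not robustness to the full messiness of array data.

`simulate_cellstage_datasets()` generates multi-study stage predictions
as stage mean + dataset intercept + residual noise; defaults (stage
means 75.6/79.1/83.2 dpc, intercept sd 5, residual sd 7, pooled sizes
30 iPSC / 4 NPC / 48 neurons across 5 datasets) mirror a typical pooled
iPSC-neuron design, making the mixed model's recovery measurable against
a known truth of +7.6 dpc for neurons.

## Problem sizes and tolerances

The test suite runs the full training check at 200 × 2000 with 10-fold
CV (seconds on one core), the type-I-error simulation at 500 replicates
of n = 200, and the meta-analysis recovery at 100 replicates of the
pooled 82-sample design — sizes chosen so the entire suite completes in
well under a minute while leaving the statistical checks adequately
powered. Solver optimality is asserted at a KKT violation below 1e-4
(the solver is run at a much tighter convergence threshold, 1e-16);
closed-form comparisons use 1e-6, exact arithmetic and round-trips
1e-10 to 1e-12.

## Known limitations

* QC starts from exported matrices; IDAT parsing and control-probe
  bisulfite-conversion metrics are out of scope, so the upstream
  "low-intensity sample" exclusion is reduced to a configurable
  median-intensity floor, off by default.
* No batch correction, cell-composition deconvolution, or functional
  normalization; these belong upstream of this package.
* Third-party clock coefficient sets are user-supplied files (the
  two-column term/coefficient format with `#key=value` metadata), not
  bundled data, with the reshaping documented in `?read_clock`.
* Mixed-model inference is asymptotic (Wald z); with very few datasets,
  treat borderline p-values with caution.
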
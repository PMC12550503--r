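---
title: "Methods: correlation-windowed imputation and horizon-specific sepsis risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-windowed imputation and horizon-specific sepsis risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sepsiswatch)
```

This vignette is the package's own account of the science it implements:
the model at each stage, the assumptions behind it, the parameters that
matter, and the places where the design was genuinely open and a choice
had to be made.

## The problem

Pediatric EHR time series are irregular on two axes. Within an episode,
each variable has its own sampling clock — heart rate every few hours,
coagulation panels daily or slower — and across episodes, whole variables
are simply never measured for some children. A risk model that scores an
episode every hour therefore needs (i) a principled notion of how far back
in time each variable's measurements remain informative, and (ii) an
imputation onto a common hourly grid that respects both within-variable
dynamics and between-variable correlation. Prediction is horizon-specific:
"will sepsis onset occur *T* hours from now?" is a different supervised
problem for every *T*, so the package trains one model per integer horizon
0–12 h.

All times are hours relative to an episode anchor (admission = 0). Each
episode has a *reference time*: the sepsis onset for septic episodes, and
a stored anchor for controls. Every trailing window, grid and cutoff is
measured back from it.

## Stage 1: windows from sampling statistics (CTWH)

**Window size.** For variable *v*, consecutive within-episode
inter-observation gaps are pooled across the cohort and the window size
*W~v~* is their 70% quantile (`quantile_q = 0.70`), using linear
interpolation between closest order statistics (R type-7; frozen so the
estimate is reproducible). The 70% quantile is deliberately above the
median: the window should be wide enough that most inter-measurement gaps
fit inside one window, otherwise most windows are empty. An alternative
pooling (quantile of per-episode median gaps) is exposed via
`ctwh_config(interval_pooling = "per_episode_median")` for cohorts where
a few densely sampled patients would otherwise dominate.

**Window count.** Windows *T~k~ = [ref − (k+1)W, ref − kW)* are stacked
back from the reference time and summarised by the arithmetic mean of the
observations they contain (mean rather than last-value or median: it is
the minimum-variance summary under additive noise). For each lag *k* the
pairs (*T₀*, *T~k~*) are correlated across episodes, complete pairs only.
The window count is

> *N* = 1 + the number of consecutive lags from lag 1 whose Pearson *r*
> exceeds `r_threshold = 0.6`,

capped at `max_windows = 4`. The current window is always usable, so
*N* ≥ 1 even for white-noise variables. The rule is *sequential* — it
stops at the first failing lag rather than taking the largest passing lag
anywhere — so the referenced history can never contain a gap of
low-correlation windows. The interpolation span is *W·N*; a variable with
a 10.3 h window whose lag-1 correlation passes but lag-2 fails spans
~20.6 h. Fewer than `min_pairs = 10` complete pairs at lag 1 forces
*N* = 1 with a warning rather than trusting a correlation estimated from
almost nothing.

**Missingness filter.** A variable missing (no observation at all) in
strictly more than 20% of episodes is excluded before windowing. The
inequality is strict — a variable missing in exactly 20% of episodes is
retained — and is tested at that boundary.

## Stage 2: multivariate GP imputation, merged with the windowed estimate

Values are standardized per variable by population moments. The latent
process is a zero-mean GP over (time, variable) with covariance

  k((t, i), (t′, j)) = σ² · B[i, j] · κ(t/ℓ~i~ − t′/ℓ~j~)

where κ is the exponential (Ornstein–Uhlenbeck) kernel by default —
physiologic signals are rough, and the OU sample paths match that — with
a squared-exponential option. Mapping each variable's time axis by its own
length scale ℓ~i~ before applying a stationary kernel keeps the matrix
positive semi-definite (it is a kernel composed with a feature map,
Hadamard-multiplied with the PSD task matrix **B**) while letting slow
labs and fast vitals carry different coherence scales. ℓ~i~ defaults to
the variable's CTWH window size *W~i~*, deliberately coupling the two
stages: *W~i~* is the pipeline's own estimate of the variable's temporal
coherence.

**Task covariance.** **B** is a rank-`task_rank` (default 5) spectral
approximation of the empirical between-variable correlation of
per-episode variable means, completed with a diagonal and renormalized to
unit diagonal. The scalar signal variance σ² and the observation-noise
variance are then set by maximizing the summed log marginal likelihood
over a subsample of episodes (`n_fit_episodes = 10`, L-BFGS-B on
log-variances, at most `max_opt_iter = 50` iterations). Optimizing the
~170 free factor parameters of a 28-variable rank-5 **B** per fit would
be slow and numerically fragile at this scale; the moment-based estimate
is stable, and the two optimized scalars are the parameters the posterior
is actually sensitive to.

**Conditioning and spans.** The posterior for an episode conditions only
on observations within each variable's span of the imputation reference
time. Grid cells beyond a variable's span take the population median and
are flagged `out_of_span` — limited-range interpolation is the entire
point of the span rule, so the GP is not allowed to extrapolate past it.
Numerical hygiene: jitter starts at `1e-6` and escalates tenfold to at
most `1e-2` before the fit fails with the episode id; an episode with no
usable observations is flagged and filled with medians.

**Merge.** At each grid cell the GP posterior mean *m* is combined with
the correlation-weighted windowed estimate *c* (per-window means weighted
by the fitted lag correlations, lag-0 weight 1, negative correlations
clipped to zero) as λ·c + (1 − λ)·m with λ = (fraction of non-empty
windows) × `fixed_weight` (default 0.5) in the default `"correlation"`
mode. The combination rule itself was an open design point — only the
weighting idea is fixed by the method's description — so both the rule
and λ are config-exposed and the provenance of every cell (`observed`,
`ctwh_merge`, `mgp`, `out_of_span`, `median_fallback`) is recorded in the
grid.

**Causality.** `impute_cohort()` smooths each episode once around its
reference time — fine for display, but a grid cell at *ref − 20* h would
then be informed by observations near *ref*. Training or evaluating
horizon *T* on such cells leaks post-cutoff information backwards through
the GP. `impute_horizons()` therefore re-imputes each episode per
horizon, with the cutoff *ref − T* as the imputation reference, so only
observations at or before the cutoff condition the posterior. The replay
simulator and `predict_risk()` do the same thing with the replay step as
the reference. The anti-leakage tests poison post-cutoff data and assert
bit-identical features.

## Stage 3: the horizon model bank

For horizon *T*, each episode contributes one row built from the trailing
12 h window ending at *ref − T*: per variable the last value, mean, min,
max and least-squares slope (a compact, standard summary set; the exact
set is config-visible), plus age, sex, weight and any-before-cutoff
indicators for antibiotics, vasopressors, glucocorticoids and mechanical
ventilation. Sequence mode keeps the 13-point hourly grid tensor instead.
One anchor per control episode is used (the alternative — multiple
cutoffs per control — is a documented convention choice, not a
requirement of the method).

Three variants share this interface:

* `tabular_boosted` — gradient boosting (xgboost), hyperparameters chosen
  by 5-fold cross-validation over a small grid (η ∈ {0.05, 0.1, 0.3},
  depth ∈ {3, 4, 6}) with early stopping at 10 rounds, then refit at the
  best round count; single-threaded and seeded so training is
  reproducible.
* `sequence_recurrent` — a two-layer gated-recurrent-unit encoder
  (64 hidden units per layer by default) with a logistic head, written
  directly in R matrix algebra: full-batch Adam on binary cross-entropy,
  backpropagation through time, early stopping on a stratified 20%
  holdout. At 13 timesteps and desk-scale cohorts, full-batch training is
  both deterministic and fast.
* `hybrid_embedding` — the encoder's final hidden state concatenated with
  the static features, fed to the boosted classifier; the schema hash is
  checked at prediction time.

## Stage 4: evaluation, attribution, alerting

AUROC is computed via the Mann–Whitney identity (ties at half credit);
AUPRC uses the average-precision (step) convention — conventions differ
between packages, so the choice is documented and oracle-tested. The
operating threshold is the score maximizing the Youden index on the
evaluation scores; sensitivity, specificity, accuracy and *J* are
reported at it. Confidence intervals are percentile-bootstrap (default
`B = 1000`), resampling episodes stratified by class; percentile rather
than BCa for parity with common practice, with *B* and the method
recorded. Tree models get exact tree-path Shapley attributions (local
accuracy to machine precision on the margin scale); the hybrid pipeline
gets permutation-sampling Shapley values whose Monte-Carlo error shrinks
with `nsim`.

Two alert tier schemes ship: scheme A (low [0.5, 0.6), medium
[0.6, 0.8), high [0.8, ∞), closed-below intervals) and scheme B (tier 1
> 0.65, tier 2 > 0.80, tier 3 > 0.90, highest matching tier). Both
appear in deployment descriptions of this class of system and they are
not mutually consistent, so neither is privileged; scheme A is the
default. The replay emits an alert when an episode's tier first rises
above everything seen so far; lead time is onset minus first qualifying
alert, summarised by median, IQR, maximum and alert-sensitivity.
Episode-level agreement binarizes an episode as alert-positive iff any
qualifying alert fired, then applies Cohen's κ — the binarization is a
package convention (configurable), since none is fixed by the method.
The replay reports the T = 0 model's score at each step; the other 12
horizons are available through `predict_risk()`.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not any real hospital's data:

* two classes with exact prevalence by permutation
  (`floor(n × 0.262)` septic by default);
* 28 dynamic variables, each with log-normal inter-measurement intervals
  whose 70% quantile is set per variable (dense vitals, sparse labs),
  per-variable episode-level missingness, and values =
  baseline + stable episode effect + Ornstein–Uhlenbeck trajectory +
  white noise, clipped to plausible ranges — the OU component is what
  gives successive windows their decaying correlation;
* a deterioration signature in septic episodes: linear drifts over the
  final `drift_duration_h` (default 6) hours before onset — lactate,
  heart rate, respiratory rate, WBC and creatinine up; blood pressures,
  pH and GCS down;
* onset drawn uniformly in [18, 60] h after admission so a full trailing
  window always exists; controls draw an anchor from the same range (a
  stated convention — no reference-time definition for controls exists
  to copy);
* onset-locked intervention events for septic episodes and a background
  antibiotic rate for controls.

What it does **not** emulate: age-dependent reference ranges, circadian
rhythm, documentation artefacts (unit errors, duplicated charting),
informative sampling (sicker patients measured more often), or any
pharmacokinetics. Passing tests on this generator therefore demonstrate
that the pipeline's machinery is correct and that it recovers structure
it is designed to see — not that any particular discrimination level
would be achieved on real cohorts.

## Problem sizes and numerical choices in the test suite

The suite exercises the stages at sizes chosen to make the statistical
assertions decisive while staying desk-scale: window-count recovery uses
AR(1)-structured cohorts of 500 episodes (lag-1 correlation 0.7, so the
rule's analytic answer is 2 windows) over 10 replicates; interval-quantile
recovery uses 200 episodes; bootstrap coverage of a known AUROC
(binormal scores, n = 100 per repetition) uses 200 repetitions at
B = 500; the held-out-imputation comparison masks 20% of trailing-window
observations in a 200-episode cohort; and the end-to-end
horizon-decay property averages 13-horizon AUROC curves over five
generator seeds at 130 episodes each, with the deterioration ramp
stretched to 12 h so the signal fades gradually across the whole horizon
range. GP oracle agreement is asserted at 1e-8 on ten-point problems,
AUROC against exhaustive pair counting at 1e-12, and tree Shapley local
accuracy at the float32 margin precision of the underlying library.

## Known limitations

* The GP is conditioned per episode with population-level
  hyperparameters; episodes with idiosyncratic dynamics inherit the
  population's length scales.
* The task covariance is estimated from per-episode means, which captures
  between-episode correlation structure; fast within-episode
  cross-variable coupling is only represented through the shared low-rank
  factor.
* The GRU encoder is full-batch and CPU-bound; it is meant for cohorts of
  hundreds to a few thousand episodes, not for GPU-scale corpora.
* Tier schemes, the κ binarization and the merge rule are conventions
  exposed in configuration; conclusions that depend on them should be
  checked under the alternatives.
* Lead-time and agreement statistics from the replay describe model
  behaviour on historical data; they say nothing causal about clinician
  response or outcomes.
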
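# sepsiswatch

Hour-level early warning of pediatric sepsis from irregularly sampled
electronic health record (EHR) time series.

Children who develop sepsis in the emergency department or PICU deteriorate
over hours, but the data that would reveal it — vital signs, blood gases,
lactate, cell counts — arrive on wildly different clocks: heart rate every
few hours, creatinine once a day or slower, with whole variables missing for
many encounters. `sepsiswatch` is a research toolkit for building and
stress-testing an early-warning pipeline on exactly this kind of data. It is
aimed at clinical data scientists and methods researchers who want each
stage of such a pipeline — windowing, imputation, horizon-specific
classification, evaluation, alerting — as tested, composable, tidy R
functions rather than a monolithic script.

## The method

The pipeline has four stages:

1. **Correlation-guided time windows (CTWH).** For each variable *v*, pool
   the within-episode inter-measurement intervals and take their 70%
   quantile as the window size *W<sub>v</sub>*. Stack windows
   *T<sub>k</sub> = [ref − (k+1)W, ref − kW)* back from each episode's
   reference time, summarise each window by its mean, and correlate
   *T<sub>0</sub>* against *T<sub>k</sub>* across episodes. The window
   count *N<sub>v</sub>* grows while successive lag correlations stay above
   *r* = 0.6; the interpolation span is *W<sub>v</sub> × N<sub>v</sub>*.
2. **Multivariate Gaussian-process (MGP) imputation.** A zero-mean GP over
   (time, variable) with an Ornstein–Uhlenbeck temporal kernel on
   length-scale-mapped inputs and a low-rank cross-variable covariance is
   conditioned, per episode, on the observations inside each variable's
   span, and queried on a regular hourly grid. The posterior mean is merged
   with a correlation-weighted windowed estimate by a convex combination;
   cells beyond a variable's span fall back to the population median and
   are flagged.
3. **A bank of 13 horizon models.** For each horizon *T* = 0…12 h a
   supervised dataset is built from the trailing 12 h window ending at
   *reference − T* (windowed summaries, static features, intervention
   flags — or the hourly grid tensor), and a model is trained: gradient
   boosting on tabular features, a two-layer gated-recurrent-unit encoder
   on sequences, or the hybrid (GRU embeddings → boosting). Training
   features for horizon *T* are imputed using only observations at or
   before the cutoff.
4. **Evaluation and alerting.** AUROC, AUPRC, sensitivity, specificity,
   accuracy, Youden index *J = sens + spec − 1* and Brier score with
   percentile-bootstrap confidence intervals; exact tree Shapley
   attributions; tiered alert replay with lead-time, alert-sensitivity and
   Cohen's-κ summaries.

Because real pediatric sepsis cohorts are not publicly deposited, the
package ships a seeded synthetic-cohort generator (`simulate_cohort()`)
that emulates the statistical structure the pipeline assumes: ~26.2%
septic prevalence, 28 dynamic variables with per-variable irregular
sampling and missingness, and a pre-onset deterioration signature (rising
lactate and heart rate, falling blood pressure and pH).

## Worked example

```r
library(sepsiswatch)

cohort <- simulate_cohort(cohort_spec(n_episodes = 90, seed = 42,
                                      drift_duration_h = 12))
ids    <- cohort$episodes$episode_id
train  <- filter_episodes(cohort, ids[1:60])
test   <- filter_episodes(cohort, ids[61:90])

windows <- fit_windows(train)
head(tidy(windows), 4)
#>   variable window_size_h n_windows span_h
#> 1 T                 5.20         2  10.4
#> 2 R                 3.73         3  11.2
#> 3 HR                3.76         2   7.53
#> 4 MAP               9.01         1   9.01

cfg   <- mgp_config()
hyper <- mgp_hyperparameters(train, windows, cfg)
h     <- c(0, 6, 12)
gtr   <- impute_horizons(train, windows, cfg, hyper = hyper, horizons = h)
gte   <- impute_horizons(test,  windows, cfg, hyper = hyper, horizons = h)

bank    <- build_bank(train, gtr, horizons = h)
metrics <- evaluate_bank(bank, test, gte, B = 200, seed = 1)
metrics[, c("horizon_h", "auroc", "auroc_lo", "auroc_hi", "youden")]
#>   horizon_h auroc auroc_lo auroc_hi youden
#> 1         0 0.958    0.902    1.000  0.750
#> 2         6 0.715    0.416    0.972  0.417
#> 3        12 0.625    0.364    0.823  0.292
```

Each row is one forecast horizon evaluated on the held-out episodes: at
diagnosis time (T = 0) the classifier separates septic from control
episodes almost perfectly (AUROC 0.958); six and twelve hours ahead the
deterioration signal is progressively fainter and discrimination decays
toward chance — the qualitative signature this kind of model bank shows on
real cohorts. `youden(0.818, 0.828)` returns `0.646`, the package's
one-line recomputation of a reported operating point.

`autoplot(metrics)` draws the AUROC-versus-horizon curve with its
bootstrap ribbon; `shapley_attributions(bank$models[["0"]]$booster, ...)`
ranks the features driving the horizon-0 score, and
`simulate_alerts()` / `lead_time_summary()` replay episodes hour by hour
against a tier scheme.

A thin command-line wrapper over these functions is installed at
`inst/cli/sepsiswatch.R` with subcommands `synth`, `fit-windows`,
`impute`, `features`, `train`, `evaluate` and `simulate-alerts`.

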
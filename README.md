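# betabursts

Transient beta-burst analysis of resting-state sensorimotor signals.

Beta-band (13–30 Hz) activity in sensorimotor cortex is not a steady
oscillation: it occurs as brief, high-amplitude bursts lasting about one to
a few beta cycles. Average spectral power cannot distinguish a change in
sustained oscillation amplitude from a change in the **rate** or
**amplitude** of these bursts — a distinction that matters in Parkinson's
disease, where beta activity tracks dopamine state and motor symptoms.
`betabursts` is for electrophysiologists who have a single-channel
region-of-interest (ROI) time course per subject (e.g. an SVD-combined
source estimate from sensorimotor cortex) and want a reproducible burst
analysis with its statistical models attached.

## What it computes

Given a beta-filtered signal *x(t)*, the package takes the Hilbert envelope
*A(t) = |x(t) + i·H[x](t)|* and defines bursts as excursions above a
threshold *T = k·median(A)*. The multiplier *k* is chosen data-drivenly:
for each candidate *k* the envelope is cut into consecutive 3.0 s segments,
the Pearson correlation between per-segment mean amplitude and burst count
is computed per record and averaged across records, and *k\** maximizes this
correlation. Each burst's duration is measured between the outward
half-maximum crossings of its peak; features per record are the burst rate
(min⁻¹), half-max duration, inter-burst interval, and peak amplitude.

Around this core:

- zero-phase FIR band-pass (13–30 Hz, transition bands 3.25/7.5 Hz) and
  SVD-based ROI combination (`bandpass_beta`, `hilbert_envelope`,
  `combine_roi`);
- Welch PSD (3 s Hann segments, 50 % overlap, 1–48 Hz), relative beta
  power, and an aperiodic-1/f + Gaussian-peak decomposition of the log
  spectrum, `log₁₀P(f) = b − χ·log₁₀f + Σ gᵢ(f)`, at most 8 peaks
  (`welch_psd`, `relative_band_power`, `fit_aperiodic_periodic`);
- mixed-effects Poisson and (shifted-)lognormal models of the burst
  features with BIC-approximate Bayes factors, and per-factor Poisson
  regressions of clinical scores on burst rate, reported as percent change
  per +10 bursts/min (`fit_rate_model`, `fit_feature_model`,
  `fit_symptom_models`, `approx_bf`, `exceedance_prob`);
- ROC/AUC classification per feature (midrank Mann–Whitney, Youden
  cut-offs) and a threshold-sweep robustness analysis (`roc_for_feature`,
  `roc_suite`, `threshold_sweep`);
- a synthetic cohort generator — 1/f noise plus Gaussian-windowed beta
  events with group-level rate distributions and Poisson-linked clinical
  scores — so the whole pipeline runs without patient data
  (`gen_cohort`, `gen_clinical_scores`, `run_simulate`, `run_analyze`).

See `vignettes/beta-burst-methods.Rmd` for the model details and design
choices.

## Worked example

Simulate the default synthetic study — 19 "patients" (106 ± 8 bursts/min,
1/f exponent 0.8) and 19 "controls" (120 ± 11, exponent 0.6), two sessions,
3 min at 1000 Hz — and run the full analysis:

```r
library(betabursts)
cohort <- run_simulate(default_config(), seed = 11)
res <- run_analyze(cohort, default_config())
print(res)
#> <burst_analysis>
#> <threshold_grid> k in [1, 5] (41 values), k* = 2.4 (mean r = 0.728)
#>   patient session 1: rate 70.3/min (SD 3.8), median duration 72 ms
#>   patient session 2: rate 70.5/min (SD 3.7), median duration 72 ms
#>   control session 1: rate 73.9/min (SD 6.0), median duration 72 ms
#>   control session 2: rate 73.7/min (SD 3.8), median duration 75 ms
#> <model_result>
#>   group:patient        -4.6% (95% CI -7.5 to -1.6), P = 0.00127
#>   session:2            +0.0% (95% CI -3.0 to +3.2), P = 0.491
#>   BF group 10.9 | session 0.115 | interaction 0.117
```

Reading this: the amplitude/count correlation selects a threshold of 2.4
envelope medians; at that threshold detected bursts have a ~72–75 ms median
half-max duration in every group and session (duration is an emergent
property of the 13–30 Hz envelope, not something the threshold tunes); the
patients show a significantly lower detected burst rate (−4.6 %, exceedance
probability P ≈ 0.001) with conclusive model evidence for a group effect
(BF ≈ 11) and against session or interaction effects (BF ≈ 0.1). Detected
rates sit below the planted generative rates because only events clearing
2.4 medians are counted.

```r
res$symptom_effects[, c("factor", "pct_change_per_10", "pct_lo", "pct_hi", "p_prob")]
#>            factor pct_change_per_10    pct_lo    pct_hi       p_prob
#> 1         midline         -5.414615 -36.96875  41.93587 0.3940349324
#> 2     rest_tremor         13.349226 -29.61399  82.53694 0.3031273866
#> 3        rigidity        -10.371067 -38.67152  30.98882 0.2858394866
#> 4    bradykinesia        -15.759242 -35.89321  10.69819 0.1092329882
#> 5 postural_tremor        -53.974679 -71.67023 -25.22601 0.0008620393
#> 6      lower_limb        -26.695638 -55.56336  20.92565 0.1119958273
```

The generator plants a −28 % bradykinesia and −40 % postural/kinetic tremor
effect per +10 bursts/min on the *generative* rates; regressing on
*detected* rates recovers rate-linked factors (negative estimates, small
exceedance probabilities for the strong effect) with attenuation and
sampling noise at n = 19 — the confidence intervals cover the planted
values.

A thin CLI wraps the same functions:

```sh
exec/betabursts simulate --seed 1 --out sim_out
exec/betabursts analyze --manifest sim_out/manifest.tsv --out results_out
exec/betabursts sweep   --manifest sim_out/manifest.tsv --out sweep_out
```

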
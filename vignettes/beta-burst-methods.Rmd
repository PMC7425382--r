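---
title: "Detecting and modelling transient beta bursts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling transient beta bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betabursts)
```

## The problem

Beta-band (13–30 Hz) activity in sensorimotor cortex is classically
summarized by its average spectral power, but the band is not a steady
oscillation: it consists of brief, high-amplitude bursts lasting roughly one
to a few beta cycles. Averaged power confounds three distinct changes — the
amplitude of a sustained rhythm, the rate of transient bursts, and the
amplitude of those bursts. In Parkinson's disease, where beta-band changes
track dopamine state and motor symptoms, distinguishing these matters: a
reduced burst *rate* with preserved burst morphology points at the drive
that initiates bursts, not at the cortical burst generator itself.

`betabursts` implements a resting-state burst analysis for single-channel
region-of-interest (ROI) time courses: a data-driven amplitude threshold on
the Hilbert envelope of the beta-filtered signal, four burst features (rate,
half-max duration, inter-burst interval, peak amplitude), the
frequency-domain counterparts (Welch PSD, relative beta power, aperiodic 1/f
parameterization with Gaussian peaks), mixed-effects group and
symptom-severity models with approximate Bayes factors, ROC classification,
and a threshold-sweep robustness analysis. A synthetic cohort generator
makes every stage testable without patient recordings.

## Signal chain

**ROI combination.** When a source-space matrix is available,
`combine_roi()` reduces it to one time course: the first right-singular
vector of the SVD scaled by its singular value, sign-normalized against the
source orientations so that flipping all sources and orientations leaves the
output unchanged. Noise-normalized source estimates carry no absolute
physical unit, so all amplitude-bearing outputs are unit-relative.

**Band-pass filter.** A zero-phase FIR band-pass at 13–30 Hz with transition
bandwidths of 3.25 Hz (lower edge) and 7.5 Hz (upper edge). A single
symmetric windowed-sinc filter cannot realize two different transition
widths, so the filter is built as the difference of two Hamming-windowed
sinc low-pass filters whose lengths are set independently by each transition
width (the Hamming rule, transition ≈ 3.3/N cycles per sample, ≈53 dB
stop-band). Zero phase is achieved by one pass with the group delay
compensated exactly — rather than forward–backward filtering — which keeps
the stated transition widths from being squared.

**Envelope.** The magnitude of the FFT-based analytic signal. The first and
last second are trimmed (`edge_trim_s = 1`, configurable) before any
threshold or burst computation, removing filter and Hilbert edge transients;
with a ~1 s filter this is the scale of the impulse-response support.

## Burst definition

The threshold is expressed in multiples *k* of the envelope median,
`T = k · median`, so it adapts to each record's dynamic range while keeping
the group-level definition fixed. The sweep from the median (k = 1) to five
times the median (k = 5) in steps of 0.1 fixes the parameterization; an
additive variant (`median + k·median`) and mean/mode center statistics are
available behind config switches but only the multiplicative median form is
asserted by the tests.

**Selection of k.** For each candidate k and each record, the envelope is cut
into consecutive non-overlapping 3.0 s segments (remainder dropped); the
Pearson correlation between per-segment mean amplitude and per-segment burst
count (an event belongs to the segment containing its peak) is computed, and
correlations are averaged across records. The selected k* maximizes this
mean correlation (first maximum on ties). At very low k almost every segment
is saturated with events and the correlation is weak or negative; at very
high k counts are sparse and noisy; the optimum sits in between. Records
with zero count variance at some k contribute no correlation there and are
excluded from that k's average (with a warning) rather than entered as 0,
which would bias the average toward zero.

**Events.** Every envelope local maximum above threshold is a candidate
burst. Onset and offset are the first outward crossings of half the peak
amplitude, linearly interpolated to sub-sample times; duration is
offset − onset (for an isolated Gaussian-shaped excursion this equals the
Gaussian FWHM, which the tests exploit as an exact oracle). Candidates whose
half-max window is cut by the record edge are discarded (at most a couple
per record). Candidates with overlapping half-max windows are merged keeping
the larger peak, greedily in descending peak order, so reported events are
disjoint. Two consequences were design goals: the event count is provably
non-increasing in k (a survivor's fate depends only on larger candidates,
which are present at every threshold below its own peak), and the
inter-burst interval — next onset minus current offset — is never negative.
Detection is scale-invariant: rescaling the envelope changes peak amplitudes
proportionally and nothing else.

## Spectral counterpart

`welch_psd()` averages Hann-tapered periodograms over 3 s segments with 50%
overlap, restricted to 1–48 Hz, density-scaled so band integrals match
band-limited variance. `relative_band_power()` is the trapezoidal integral
over 13–30 Hz divided by the 1–48 Hz integral, with the band edges
interpolated onto the grid; it is invariant to global scaling and has exact
closed forms for flat (17/47) and 1/f (ln(30/13)/ln 48) spectra used as test
oracles.

`fit_aperiodic_periodic()` decomposes log10 power: a robust log–log linear
fit (OLS, refit excluding top-quartile positive residuals so narrow-band
peaks do not bias the line), then up to eight Gaussians — log10-power height
over linear frequency — fitted iteratively to the largest remaining residual
peak, then an aperiodic refit on the peak-subtracted spectrum. The peak
criterion is 2 SD of the current flattened residual with an absolute floor
of 0.01 log10 units (~2% power) so numerically exact power laws yield zero
peaks; widths are bounded to [1, 12] Hz. The exponent is stored positive for
1/f-type spectra (model `log10 P = intercept − χ·log10 f`, intercept at
1 Hz). The largest fitted peak with center in 13–30 Hz supplies the beta
peak frequency and height; absence of such a peak is reported as `NA`,
distinct from zero. Knee-form aperiodic fitting is out of scope — resting
cortical spectra over 1–48 Hz are adequately described by the fixed form.

## Group and symptom models

The published analysis used Bayesian mixed models estimated by MCMC. This
package replaces that machinery with deterministic approximations that
preserve the decision structure at desk scale:

* **Rate model.** Poisson GLMM (Laplace approximation, `lme4`) of per-record
  burst counts on Group + Session with a subject random intercept and
  log(analyzed minutes) as exposure offset. All records here are equal
  length, so the offset is inert, but it keeps the model correct for
  unequal-length inputs.
* **Per-event features.** Durations and peak amplitudes: shifted-lognormal
  mixed models, the shift profiled on a coarse 25-point grid over
  [0, 0.99·min] by profile likelihood (including the change-of-variable
  Jacobian); fixing the shift to 0 reduces exactly to the lognormal model
  used for inter-burst intervals. Effects are percent changes of the median.
* **Bayes factors.** BIC approximation, `BF = exp((BIC₀ − BIC₁)/2)`, between
  models with and without each factor. Exact posterior Bayes factors depend
  on priors and integration; the BIC form is deterministic and agrees
  ordinally (above/below 1 and 3), which is what the analysis consumes. A
  model compared against itself gives exactly 1.
* **Exceedance probability.** The analogue of "95% of the posterior excludes
  zero": the sign-opposite tail mass of the contrast, from Monte-Carlo draws
  of its asymptotic Gaussian (or the analytic tail). Refitting the GLMM
  thousands of times for a bootstrap would change third decimals at hundreds
  of times the cost; the Gaussian draws agree with the analytic tail within
  0.02 by construction.
* **Symptom models.** One Poisson GLMM per clinical factor: score on burst
  rate (scaled by 10, so the coefficient is per +10 bursts/min) with subject
  and session random intercepts, patients only. With two sessions the
  session variance is weakly identified; when it collapses to zero the model
  falls back to a fixed session effect, recorded in the output. Effects are
  reported as `100·(exp(10β) − 1)` percent per +10 bursts/min.

## Classification

`roc_for_feature()` fits a univariate logistic regression and computes the
AUC of its scores exactly as the midrank Mann–Whitney statistic —
tie-robust, and identical to trapezoidal integration of the empirical ROC.
The optimal cut-off maximizes Youden's J (ties resolved to the lower value);
an accuracy criterion is available since the published "optimal threshold"
criterion is not stated. The ROC is apparent (in-sample), as in the original
analysis, and therefore optimistic; no cross-validation is attempted.
`threshold_sweep()` repeats detection, the rate model, the Bayes factors and
the per-session AUC at every k of the grid; its row at k* reproduces the
primary outputs exactly.

## The synthetic cohort

The generator defines the study conditions rather than a tunable benchmark:

* **Noise.** 1/f noise with PSD ∝ f^−χ, synthesized by frequency-domain
  shaping of white Gaussian noise (amplitude ∝ f^(−χ/2), DC zeroed),
  rescaled to unit SD. Default exponents: 0.8 (patients), 0.6 (controls),
  matching the groups' fitted slopes.
* **Bursts.** A homogeneous Poisson process of Gaussian-windowed sinusoids;
  carrier frequency uniform in 13–30 Hz, envelope FWHM normal with mean
  75 ms and SD 25 ms (truncated at 20 ms), matching the reported duration
  distribution. The Gaussian window makes the downstream half-max duration
  analytically known.
* **Rates.** Subject-level rates Normal(106, 8) for patients and
  Normal(120, 11) for controls (bursts/min), truncated at zero rather than
  redrawn; session 2 keeps the subject's rate (an additive session offset is
  configurable, default 0, since no conclusive session effect on rate was
  found).
* **Amplitude.** The one free calibration: events are planted at peak
  amplitude 1.0 (SD 0.4, truncated at 0) in units where the broadband noise
  has unit SD — the same order as the reported ~1.0 peak amplitudes in
  noise-normalized source units. In this regime the optimized threshold
  lands at k* ≈ 2.2–2.7 and the pooled median half-max duration of detected
  events is 71–75 ms with a 95% range of roughly 46–163 ms, reproducing the
  reported duration distribution as an emergent property. This was fixed
  once and is not revisited.
* **Clinical scores.** Poisson draws with log-mean linear in the burst rate:
  `score ~ Poisson(exp(a + β·rate))`, `β = ln(1 + pct/100)/10`. Defaults
  plant the reported effects — bradykinesia −28% and postural/kinetic tremor
  −40% per +10 bursts/min — with factor means (12, 4, and 3–6 for the
  rate-independent factors) chosen once to emulate a moderate off-medication
  cohort (total motor score ≈ 30). No overdispersion is simulated.

What the generator does *not* emulate: multichannel sensor data, artifacts
(cardiac, ocular, movement), non-stationary or autocorrelated burst
processes, burst waveform asymmetries, and any coupling between burst
amplitude and rate. Passing tests therefore demonstrate that the pipeline
recovers what it is designed to measure under the stated generative model,
not that detection is robust to every property of real MEG.

## Numerical choices and degenerate inputs

Sub-seeds for every stochastic stage derive from one master seed by a fixed
affine-modular scheme (`derive_seed()`), so stages can be re-run in
isolation and whole runs are bit-reproducible. Thresholds below the median
(k < 1), empty envelopes, all-zero source matrices, bands outside the PSD
range, non-positive powers, single-class ROC inputs and degenerate
(zero-variance) contrasts raise errors; all-zero clinical factors are
skipped with a warning. Ties: first maximum for k*, lower value for ROC
cut-offs, first sample for envelope plateaus.

## Problem sizes

The test suite and the acceptance script run the full-resolution study
conditions (19 records × 180 s × 1000 Hz) for the emergent-duration
analysis, and count-level or rate-level simulation — which is exact for
those models — for classifier and regression recovery (51 and 20 replicate
cohorts). Module tests use shorter records (10–40 s) at reduced sampling
rates; every quantitative claim above is asserted by a test at the stated
tolerance, and nothing else is claimed.

## Known limitations

* BIC Bayes factors approximate the published prior-dependent BFs only
  ordinally; exact magnitudes (which reached 10⁹ on the real data) are not
  reproducible and not asserted.
* The apparent ROC overstates out-of-sample performance.
* The shifted-lognormal shift is profiled, not jointly estimated, and its
  uncertainty is not propagated.
* With two sessions, the session random intercept is weakly identified; the
  fixed-effect fallback changes the estimand slightly.
* Emergent duration statistics depend on the filter's bandwidth; a
  differently designed 13–30 Hz filter (e.g. forward–backward application)
  would shift the noise-driven duration floor by a few milliseconds.
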
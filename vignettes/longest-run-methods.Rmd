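---
title: "Longest-run Monte Carlo inference for somatosensory evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longest-run Monte Carlo inference for somatosensory evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicarsep)
```

## The inferential problem

Event-related potential (ERP) experiments compare two condition waveforms
sampled densely in time. A one-sample *t*-test of the per-participant
difference waveform at every time point — here 101 points across 0–200 ms
at 500 Hz — multiplies the comparison a hundredfold, and classical
corrections (Bonferroni, FDR) ignore the strong temporal dependence of EEG:
neighbouring samples are nearly identical, so chance excursions of the
*t*-statistic persist for many consecutive samples.

The procedure implemented in `sep_runtest()` controls the familywise error
by calibrating the *duration* of significant runs rather than the height of
the pointwise statistic:

1. estimate the lag-1 autocorrelation $\rho$ of each participant's
   difference waveform over the analysis window and average across
   participants (`estimate_rho()`);
2. simulate 1000 null data sets, each with the same number of participants
   and time samples, every waveform a stationary Gaussian AR(1) series
   $x_t = \rho x_{t-1} + \sqrt{1-\rho^2}\,\varepsilon_t$ with zero mean and
   unit variance at every point (`simulate_null()`);
3. in each simulated data set run the pointwise two-tailed *t*-tests at
   $\alpha = 0.05$ (uncorrected) and record the longest run of consecutive
   significant samples;
4. take the nearest-rank 95th percentile of the 1000 longest-run lengths as
   the duration threshold, and declare significant any observed run that is
   *strictly longer* (`significant_intervals()`).

Because the null model reproduces both the pointwise size of the test and
the temporal persistence of chance runs, a single waveform comparison keeps
its type-I error near the nominal 5% without any pointwise correction.
With $n = 15$ participants and 101 samples at 2 ms spacing, the threshold
is roughly 44 ms of consecutive significance at $\rho = 0.99$, 38 ms at
0.98 and 34 ms at 0.97 — higher autocorrelation makes longer chance runs,
so the bar rises with $\rho$ (a monotonicity the test suite asserts).

The same entry point serves the three comparisons of interest: the
contralateral Hand−Surface difference, the ipsilateral difference, and
their row-wise double difference (the condition-by-hemisphere
interaction, `build_interaction_matrix()`).

## Numerical choices

* **Percentile.** Nearest rank on the sorted run lengths
  ($\lceil 0.95\,n_{\text{sims}}\rceil$-th order statistic): deterministic,
  no interpolation ambiguity, and an integer number of samples.
* **Strict exceedance.** A run exactly equal to the threshold is *not*
  significant; only strictly longer runs are reported.
* **Which $\rho$ feeds the simulation.** `estimate_rho()` reports the
  average rounded to two decimals but `sep_runtest()` simulates at the raw
  (unrounded) average; `rho` can be overridden to reproduce a printed
  two-decimal value exactly.
* **Random streams.** `simulate_null()` draws innovations in contiguous
  per-simulation blocks under a single seed, so enlarging `n_sims` extends
  the null distribution without reshuffling earlier simulations.
* **Degenerate columns.** A zero-variance sample is significant when its
  common value is non-zero (infinite *t*, flagged) and not significant when
  it is zero; a constant difference matrix leaves $\rho$ undefined and
  requires an explicit override.
* **Sample counting.** All windows are closed intervals; 0–200 ms at 500 Hz
  therefore contains 101 points, and a run of $L$ samples corresponds to
  $2L$ ms.

## A calibration caveat at very high autocorrelation

The test suite checks the familywise error rate of the *complete* procedure
(estimate $\rho$, simulate, strict exceedance) on replicate null studies of
15 AR(1) waveforms with $\rho$ in 0.97–0.99. The measured rate is about
0.12–0.14, not 0.05. The cause is estimation bias, not a coding defect:
the mean-centred sample lag-1 autocorrelation of a 101-point window is
biased downward (expectation ≈ 0.92 when the true $\rho$ is 0.99), the null
is therefore simulated at too low a persistence, and genuine chance runs
exceed its threshold too often. The bias shrinks quickly at moderate
autocorrelation — the same experiment at $\rho = 0.3$ is within the nominal
band — and matters little for *detection* of real effects, but the nominal
5% guarantee should not be taken literally when difference waveforms are as
smooth as heavily low-pass-filtered infant EEG. Supplying a known `rho`
restores calibration (the corresponding check runs at ≈ 0.03–0.05). We
report this honestly rather than adjusting the estimator, because the
mean-centred per-participant estimator is the field's standard reading.

Interestingly, the bias is partly masked on the synthetic studies below:
30 Hz low-pass filtering raises the true lag-1 autocorrelation of the
averaged difference waveforms above the raw noise value of 0.99, so the
biased estimate still lands near 0.98–0.99.

## The synthetic study generator

No infant EEG ships with this package; `simulate_study()` generates studies
with the statistical structure the analysis assumes, so every stage is
testable end to end.

* **Design.** 15 participants; 25 trials per condition (Hand / Surface);
  the stimulated hand balanced within condition; epochs −100 to +700 ms at
  500 Hz; 16 channels — the six analysis electrodes (41, 46, 47 left;
  98, 102, 103 right, around CP3/CP4) plus 10 noise-only channels so
  average referencing has a realistic denominator.
* **Noise.** Independent stationary AR(1) series per channel and trial,
  lag-1 autocorrelation 0.99, SD 5 µV. Channels are uncorrelated — a
  simplification; real EEG has strong spatial correlation.
* **Signal.** A Gaussian positive SEP template (peak 130 ms, FWHM 60 ms,
  raw amplitude 6 µV) on the six analysis electrodes, plus box-car
  condition offsets confined to 92–184 ms on the cluster contralateral to
  the stimulated hand and 66–166 ms ipsilaterally.
* **Calibrated injection.** The configured effect values (defaults: Hand
  3.06 / Surface 5.80 µV contralaterally, 0.94 / −1.07 µV ipsilaterally)
  are *post-preprocessing condition means*. Average referencing mixes the
  cluster signals (six signal-carrying channels among 16 shrink and couple
  by roughly a fifth), so the generator solves a small linear system
  against the actual noise-free preprocessing operator — filter, baseline,
  re-reference, cluster average — and injects the raw amplitudes that land
  exactly on the targets. A noise-free default study reproduces all four
  condition means to numerical precision (asserted at 1e-9 µV).
* **Heterogeneity.** Each participant's condition difference is perturbed
  by a normal draw with SD equal to 50% of the group-mean difference,
  split symmetrically across conditions, which makes group *t*-tests
  realistically noisy.
* **Artifacts.** 28% of trials receive a ±400 µV half-sine excursion on one
  random channel; the 200 µV peak-to-peak rejection criterion then retains
  about 18 trials per condition, the attrition typical of infant ERP work.
  Real blink topographies, gaze shifts and channel dropout are not
  emulated — rejection here is a transparent amplitude criterion standing
  in for visual inspection.

What passing tests on these data do *not* show: robustness to spatially
correlated noise, non-stationary noise, latency jitter across trials and
participants, or real artifact morphology. The generator is a calibration
instrument, not a forward model of infant EEG.

## Preprocessing

The chain follows standard ERP practice, in the fixed order
filter → reject → baseline → re-reference → average:

* **Filter.** Zero-phase (forward–backward) elliptic low-pass at 30 Hz.
  The default order is 5 with 0.5 dB passband ripple and 40 dB stopband
  attenuation: an odd-order elliptic filter has exactly unit DC gain,
  which preserves constant offsets and makes the baseline property exact
  (an even order would attenuate DC by the ripple, about 11% after the
  double pass). Both order and ripple are configurable. The
  forward–backward pass protects component latencies; its zero-padding
  transients are confined to the epoch edges, well away from the 0–200 ms
  analysis window. The vectorised implementation is asserted equal to the
  per-series reference (`signal::filtfilt`) at 1e-10.
* **Rejection.** Peak-to-peak amplitude over any channel strictly above
  200 µV flags the trial; a participant losing every trial of a condition
  is dropped entirely.
* **Baseline / reference.** Per-trial per-channel mean over −100–0 ms
  subtracted; then the per-sample mean across all channels. Both are
  idempotent linear operators and commute — asserted to 1e-9 µV.
* **Averaging.** Per trial, the three-electrode cluster contralateral (or
  ipsilateral) to that trial's stimulated hand is averaged, then trials are
  averaged; cluster-before-trial order is immaterial for means but fixing
  it makes tests exact. Laterality pooling is symmetric under a global
  left–right relabelling (asserted).

## Problem sizes used by the checks

The packaged tests run the threshold ladder as means over ten 1000-run
Monte Carlo batches per $\rho$; the familywise-error experiment uses 1000
replicate null studies of 15×101 waveforms with 1000 simulations each; and
parameter recovery uses 100 replicate full studies at the default effect
sizes, requiring a correctly-signed interval overlapping the true window in
at least 90% of replicates and a Jaccard overlap of at least 0.5 in the
majority. These sizes keep the full suite to roughly ten minutes on one
core while leaving Monte Carlo error well inside the asserted bands.

## Known limitations

* The familywise calibration caveat above: nominal 5% is optimistic when
  $\rho$ is estimated from short, very smooth waveforms.
* The AR(1) null describes temporal persistence by a single parameter;
  filtered EEG noise is smoother than AR(1) at matched lag-1, which the
  null cannot represent.
* One interval family per matrix: no spatial clustering across electrodes,
  no cluster-mass or max-*t* permutation alternatives.
* The generator's free parameters (noise SD, between-participant
  heterogeneity, attrition) were chosen once to sit in the regime the
  analysis assumes — unit-order variability of retained-trial averages and
  ~18 retained trials — and are configuration knobs, not estimates from
  data.
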
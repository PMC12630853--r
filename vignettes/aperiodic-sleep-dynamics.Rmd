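---
title: "Aperiodic activity in sleep: models, estimation choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aperiodic activity in sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aperisleep)
```

## The model

Neural power spectra combine oscillatory peaks with an aperiodic
background that decays with frequency. `aperisleep` models the
aperiodic component in log10 power as

$$\log_{10} L(f) = b - \log_{10}\!\left(k + f^{x}\right),$$

with offset $b$ (log10-power units), knee constant $k \ge 0$
(dimensionless) and exponent $x$. The **fixed** mode pins $k = 0$,
giving a straight line of slope $-x$ in log–log coordinates; the
**knee** mode fits the Lorentzian-style bend, whose location in
frequency is the knee frequency $f_k = k^{1/x}$ — the interpretable
quantity, often read as the dominant timescale of the underlying
population. Users therefore specify knees in Hz throughout the package;
the constant $k$ is internal. Oscillations are Gaussian components in
log power above the aperiodic background, parameterized as (center Hz,
height in log10 power, bandwidth in Hz) with the convention
**bandwidth = 2 × Gaussian SD**.

Two caveats shape interpretation. First, the knee model assumes a flat
spectrum below the knee; `pre_knee_exponent()` quantifies how flat the
sub-knee region really is by fitting a fixed model on
$[1\,\mathrm{Hz}, f_k]$. Second, fixed-mode exponents fitted to
knee-bearing spectra are *blends* of the pre- and post-knee regimes:
across spectra that differ only in knee frequency, the fixed exponent
correlates negatively with the knee frequency. Exponents from different
model forms are related but not interchangeable.

## The fitting algorithm

`fit_spectral_model()` alternates two sub-fits:

1. **Robust aperiodic fit.** A bounded least-squares fit of the
   aperiodic form (fixed mode is solved in closed form by OLS in
   log–log space; knee mode profiles the offset analytically and
   searches $(\log_{10}(k+1), x)$ with multi-start L-BFGS-B plus a
   Nelder–Mead polish). The spectrum is flattened by this fit, negative
   residuals are clipped, and the fit is repeated on the points at or
   below the 2.5th percentile of the flattened spectrum — i.e. the
   points hugging the aperiodic component, excluding peaks.
2. **Iterative peak search and refinement.** The largest maximum of the
   flattened spectrum is accepted while it exceeds
   `peak_threshold` × SD of the flattened spectrum (and
   `min_peak_height`), its width guessed from the half-height crossing,
   a Gaussian subtracted, up to `max_n_peaks` times; all Gaussians are
   then refined jointly (bounded, analytic gradients). Guesses within
   one SD of a range edge, or overlapping a neighbour by more than
   0.75 × the summed SDs, are dropped.
3. The aperiodic component is re-fitted on the peak-subtracted
   spectrum, and **steps 2–3 are alternated** (at most `n_iter = 5`
   times, stopping when the exponent changes by less than $10^{-5}$).

The iteration is the one place the package deliberately extends the
classic staged recipe: a single pass leaves the aperiodic fit biased by
whatever the initial flattening attributed to peaks (on noiseless
exact-model-class spectra the residual exponent error is ~0.05), while
alternating the two sub-fits converges to the joint solution (error
< 0.01) without changing the model class. A full joint optimization of
aperiodic and peak parameters was evaluated and rejected: on narrow
bands it absorbs estimator noise into peak parameters and makes
narrow-band fits look spuriously good.

Goodness of fit is the squared Pearson correlation between model and
data log powers over the fit range; the error metric is the mean
absolute log10-power error (MAE). `bic()` implements
$N\log(\mathrm{mse}) + n_p \log N$ (natural log) with
$\mathrm{mse} = \mathrm{MAE}^2$ and $n_p = 3\,n_\mathrm{peaks} + 2$
(fixed) or $+3$ (knee); `compare_models()` labels
$|\Delta \mathrm{BIC}|$ of 0–2 / 2–6 / >6 as weak / positive / strong
evidence.

**Defaults** (all overridable in `fit_settings()`): fit range 1–45 Hz;
peak width limits 1–12 Hz; at most 8 peaks; minimum peak height 0;
peak threshold 2 SD; exponent bounded to $[0, 8]$ and the knee constant
to $[0, f_\mathrm{hi}^{8}]$, ties across optimizer starts broken by
lowest error. At realistic estimator-noise levels the peak search will
attribute some noise maxima to peaks; this is inherent to the
threshold-based search and is why parameter-recovery analyses on
peak-free signals should set `max_n_peaks = 0`.

## PSD estimation choices

* `welch_psd()`: Hamming taper, constant detrend per segment, 15-s
  windows with 50 % overlap (frequency step 1/15 Hz), one-sided density
  in µV²/Hz.
* `sliding_psd()`: 20-s intervals advanced by 2 s (90 % overlap);
  window time stamps are **window centers**, used consistently by the
  dynamics functions.
* `multitaper_tfr()`: DPSS tapers computed from the tridiagonal
  formulation; time–bandwidth product 2 (hence 3 tapers — the count is
  a documented choice, not given by the estimation settings above);
  1–45 Hz in 0.5 Hz steps with cycles = frequency, so the analysis
  window is 1 s at every frequency; the first and last second of each
  epoch are discarded.
* `epoch_and_reject()`: 10-s epochs centered on events; trials with
  peak-to-peak amplitude above 1000 µV are masked.
* `concatenate_with_buffers()`: segments are demeaned, joined with 2-s
  zero buffers (at most 5 segments) and zero-padded to 68 s, with
  buffer/pad sample ranges recorded in provenance.
* `baseline_correct()`: subtract mode for aperiodic-parameter traces,
  relative mode `(data − baseline)/baseline` for ERPs; the baseline
  window is half-open `[t0, t1)` like every window in the package.

## Statistics

Stage comparisons use the Friedman test with Kendall's
$W = X^2/(N(K-1))$ (ties by midranks; interpretation bands 0–0.2
slight … >0.8 almost perfect), Dunn's post-hoc
$z = (\bar R_i - \bar R_j)/\sqrt{K(K+1)/(6N)}$ with Bonferroni
correction, and Cliff's delta $\mathrm{cd} = 2p - 1$ from the pairwise
dominance probability (ties count ½), with the large-sample CI
$p \pm 1.96\sqrt{p(1-p)/(n_1 n_2)}$ transformed back and clipped to
$[-1, 1]$. Broad-vs-narrow comparisons use the Wilcoxon signed-rank
test with the rank-biserial correlation $(W^+ - W^-)/(W^+ + W^-)$.
`partial_spearman()` rank-transforms both variables, residualizes on
stage indicators and correlates the residuals.

Classification uses LDA with stratified 5-fold × 2-repetition
cross-validation after seeded equalization of per-stage trial counts;
groups with fewer than 25 trials in any stage are dropped. Accuracies
are tested against chance (1/number of classes) with a label-shuffling
permutation t-test (two-sided by |t|, built by concatenating the
observations with a chance array of matching length, shuffling and
splitting); the Bonferroni family size is
always an explicit caller argument. Random-forest feature importance
permutes one feature at a time (single-predictor models, avoiding
collinearity) and reports the mean held-out accuracy drop.

`cluster_permutation_test()` forms clusters from the pointwise paired
t-trace at a two-sided p < 0.05 forming threshold (the forming
threshold is a convention choice, documented rather than prescribed),
scores them by the sum of t values, and builds a **per-tail**
max-cluster-mass null from seeded sign flips; each tail is tested at
alpha 0.025. Cohen's d for a cluster is the mean difference over the
cluster extent divided by the SD of trial-wise mean differences over
that extent (the package's definition; several are in circulation).
Under planted-null simulation the family-wise false-positive rate is
~0.05, as the two tails at 0.025 imply.

## The synthetic generator

`simulate_sleep_recording()` emulates the structure the analyses
assume, so that every downstream stage is testable without data
downloads:

* **Hypnogram**: a Markov chain over Wake/N1/N2/N3/REM in 30-s epochs
  with a plausible sleep-architecture transition matrix.
* **Stage backgrounds**: frequency-domain-shaped Gaussian noise with
  expected PSD $\propto 1/(k + f^x)$. Defaults (exponent, knee Hz):
  Wake (1.0, 10), N1 (1.3, 8), N2 (1.6, 6), N3 (2.0, 2.5),
  REM (1.2, 9) — exponents deepen toward N3 and drop into REM, knee
  frequency is lowest in N3, mirroring scalp-EEG stage patterns.
  Epochs are cross-faded over 0.5 s (real transitions are continuous).
* **Oscillations**: band-limited filtered noise (≈2 Hz bandwidth —
  pure sinusoids would produce sub-resolution peaks outside the
  model's width limits), amplitude-modulated at 50 % depth: alpha
  (10 Hz) in Wake, theta (7 Hz) in N1, spindle-band (13 Hz) in N2,
  slow activity (0.8 Hz, below the 1-Hz fit edge) in N3.
* **Stimulation**: 90-min stimulation / 30-min quiet blocks (4
  cycles, truncated to the recording), inter-stimulus intervals
  jittered over {2800, 3300, …, 7800} ms, categories from
  {SON, UN} × {FV, UFV}. Each stimulus can trigger a transient
  exponent shift (default +0.4 for 0.8 s after 0.1 s latency),
  implemented by cross-fading in an equal-variance segment with the
  shifted exponent.
* **K-complexes**: biphasic negative-then-positive waveforms (150 µV
  peak-to-peak, 0.9 s) injected in N2, spontaneously at 1/min and
  after N2 stimuli with probability 0.25 (elicitation rates near one
  in four are typical for auditory stimulation).

What the generator does **not** emulate: volume conduction and channel
covariance, EMG/EOG artifacts, epileptiform activity, non-Markovian
sleep-cycle structure, or oscillation waveform asymmetries. Passing
tests therefore validate the estimators and inference machinery under
the stated model class, not robustness to real-data artifacts.

## Numerical and design choices

* Log-power noise in simulated spectra is i.i.d. normal per frequency
  bin; the worked-example noise SD is 0.05 and its peak parameters are
  (10 Hz, 0.9, 2.5 Hz) and (30 Hz, 0.6, 5 Hz) — magnitudes typical of
  alpha/beta peaks in parameterization demonstrations.
* Time convention: seconds from recording start, half-open windows
  `[t0, t1)`; every randomized operation takes an explicit seed, and a
  pipeline master seed fans out deterministically to stage seeds.
* Degenerate inputs: SD-0 exclusion groups keep everything with a
  warning; all-zero spectrogram slices become explicit `NA` gaps;
  fully tied Friedman matrices report $W = 0$; zero-variance
  accuracies trigger an analytic fallback.
* Transition baselines are seeded random continuous same-stage 120-s
  spans that do not overlap any transition window ("adjacent
  uninterrupted sleep" admits several readings; random matched spans
  is the package's, and it is documented rather than asserted).
* Event-locked exponent traces can be computed per trial (with
  trial-mean and SEM) or on the trial-averaged time–frequency power
  (`average_trials = TRUE`); single-trial 3-taper spectra carry
  substantial estimator noise, so the averaged variant is the
  recommended estimator of response amplitude.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at desk scale: 10 noise
seeds for the worked-example fits; 20-seed ensembles for the
range-sensitivity property; synthetic nights of 100–200 epochs
(50–100 min) for stage statistics, classification and transitions;
500 replicates with 1000 permutations each for the cluster-test
calibration (the user-facing default stays at 5000 permutations);
12-epoch N2 recordings with ~100 stimuli for event-locked responses.
These sizes were chosen so each property is measured with comfortable
statistical margin; all of them scale up by changing the corresponding
arguments.

## Known limitations

* The knee model underestimates knees close to the lower fit edge
  (e.g. N3's 2.5 Hz knee against a 1-Hz edge); the exponent remains
  recoverable but knee-frequency estimates there are unstable — the
  same regime in which real N3 spectra make the knee hard to observe.
* Single-realization knee fits on Welch spectra of short (1–2 min)
  signals have wide sampling distributions; average spectra across
  epochs (or disable the peak search on peak-free signals) before
  interpreting knee frequencies.
* The fixed-mode exponent of knee-bearing data is range-dependent by
  construction; report the fit range with any exponent.
* K-complex detection is a candidate detector (amplitude, duration,
  template-correlation score); it is not a validated clinical scorer.
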
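---
title: "Discriminating favorable from unfavorable pulseless electrical activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating favorable from unfavorable pulseless electrical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaprog)
```

## The problem

Pulseless electrical activity (PEA) presents organized QRS complexes
without a palpable pulse. Some PEA episodes evolve to return of
spontaneous circulation (faPEA), others do not (unPEA), and the two call
for different resuscitation strategies. `peaprog` classifies paired 5-s
ECG / thoracic-impedance (TI) segments into faPEA/unPEA, exploiting the
physiological signature of incipient mechanical heart activity: faPEA
tends to show a more regular ECG with larger, narrower QRS complexes at a
higher rate, and — crucially — a small TI oscillation phase-locked to the
heartbeats, the impedance circulation component (ICC), reflecting
ventricular wall motion and blood flow. The ICC rarely exceeds 100 m-ohm
riding on an impedance baseline of tens of ohms, which is why its
extraction needs a model-based estimator rather than plain filtering.

## Signal model and pipeline

All segments are canonicalized to fs = 250 Hz, 1250 samples. The stages:

**ECG denoising.** 8-level stationary wavelet transform (SWT, db4 — the
8-tap Daubechies filter with 4 vanishing moments), soft thresholding,
reconstruction from detail levels d3–d8. Detail level $k$ occupies the
dyadic band $[f_s/2^{k+1}, f_s/2^k]$, so d3–d8 spans 0.49–31.25 Hz. The
SWT is implemented by circular convolution in the FFT domain; because the
analysis pair satisfies $|H(\omega)|^2 + |G(\omega)|^2 = 2$, the adjoint
filters reconstruct exactly (verified to $10^{-9}$ in the tests). The
1250-sample segment is symmetrically padded to 1280 (a multiple of
$2^8$), transformed, and cropped.

**Threshold rule.** Soft thresholding uses the universal threshold
$\hat\sigma\sqrt{2\ln N}$. The noise scale $\hat\sigma$ is the MAD
estimate taken from the *finest* detail level d1, which is
noise-dominated for band-limited physiological content. A per-level MAD
was considered and rejected: on a quasi-sinusoidal component such as the
ICC the per-level MAD measures the oscillation itself, and the resulting
threshold annihilates every kept band.

**TI preprocessing.** The TI is bandpass filtered to 0.8–10 Hz to remove
baseline wander and respiration. The filter realizes the squared-magnitude
response of a 4th-order Butterworth (what a forward–backward pass
converges to) applied in the FFT domain on the mirror-extended signal.
A recursive realization at a 0.8 Hz edge with fs = 250 Hz is badly
conditioned — edge transients of tens of percent on sub-band tones and
linearity only to $10^{-6}$ — while the spectral realization is exactly
zero-phase and linear to machine precision, which the tests check against
pass/stopband oracles.

**QRS detection and instantaneous heart rate.** A Hamilton–Tompkins
detector (8–16 Hz bandpass, derivative, rectification, 80-ms
moving-window integration, adaptive dual thresholds with search-back,
200-ms refractory period) runs on the denoised ECG; detections are refined
to the local ECG extremum. The constants were fixed once against synthetic
fixtures with known beat times. The instantaneous heart rate is expressed
as a normalized frequency in cycles/sample,
$f(n) = 1/(r_{i+1}-r_i)$ for $n \in [r_i, r_{i+1})$, held constant beyond
the first/last peak. Cycles/sample keeps the phase $2\pi f(n) n$ of the
harmonic model dimensionless and consistent.

**ICC extraction.** The ICC is modeled as a Fourier series of $K = 5$
harmonics of $f(n)$ with time-varying coefficients collected in the state
$x_n = [a_1(n) \ldots a_K(n), b_1(n) \ldots b_K(n)]^T$, observed through
the row $H_n = [\cos(k 2\pi f(n) n), \ldots, \sin(k 2\pi f(n) n)]$ against
the filtered TI sample. The coefficients follow a decaying Gaussian
process $x_n = \psi\, x_{n-1} + \omega_n$ with
$\psi = \exp(-\lambda/f_s)$, $\lambda = 0.05$, process-noise sd
$\sigma = 0.01$. Note the exponent: $\exp(-\lambda f_s)$ would be
$e^{-12.5} \approx 0$ at these values, annihilating the state at every
sample; $\exp(-\lambda/f_s) \approx 0.9998$ yields the slowly varying
coefficients the model intends. Estimation is a forward Kalman filter
plus Rauch–Tung–Striebel backward pass; the smoothed coefficients
synthesize $s_{ICC}(n) = H_n \hat x_{n|N}$, which is then SWT-denoised
keeping d5–d7 (≈1–8 Hz). Two quantities the model does not specify are
estimated per segment: the observation-noise variance as
$\mathrm{var}(\Delta \tilde{s}_{TI})/2$ (a high-frequency noise
estimator, floored at $10^{-6}$), and the initial covariance as
$\mathrm{var}(\tilde{s}_{TI})\cdot I$ — an uninformative start that the
data dominates within a few beats. If fewer than two beats are detected
the heart rate, and hence the ICC, is undefined: the eight ICC features
are set to 0 and the segment is flagged, a deterministic and auditable
degradation.

## The 17 features

From the denoised ECG (9): AMSA (frequency-weighted sum of spectral
amplitudes over 2–30 Hz, Tukey-0.1 window, coherent gain corrected;
mV·Hz), high-band power (periodogram integral over 17.5–40 Hz — content
above the 31.25 Hz reconstruction edge is negligible, so the integral is
effectively 17.5–31.25 Hz; mV²), fuzzy entropy (m = 2, r = 0.2·SD,
exponent 2, Chebyshev distances on mean-removed templates — relative
tolerance makes it amplitude-invariant), SNEO (mean Teager energy
$x_n^2 - x_{n-1}x_{n+1}$ smoothed by a unit-area 50-ms Bartlett window),
the IQR of the signal and of its soft-thresholded d5–d7 detail sequences,
and the Burg AR(4) innovation variance (low when the spectrum is
line-like, i.e. an organized rhythm). From the denoised ICC (8): log
mean-square power (guarded by $10^{-12}$), SNEO, the four IQRs, Burg
AR(4), and the ECG–ICC cross power (Welch magnitude cross-spectral
density, 1-s Hann windows, 50% overlap, integrated over 1–8 Hz and scaled
as a band power). IQRs use the type-7 (linear interpolation) quantile
convention throughout. Every feature is checked against an independent
closed-form, Parseval or simulation oracle in the test suite.

## Classifier and evaluation

The random forest uses 500 trees, each on an independent 10% bootstrap
replica (with replacement), $\lfloor\sqrt{D}\rfloor$ candidate predictors
per node, terminal nodes of at least 5 observations, and uniform class
priors. "Uniform priors" is realized as balanced weighting applied twice:
balanced case weights make each bootstrap replica class-balanced in
expectation, and balanced class weights keep the split criterion
prior-free; the tests verify that duplicating minority rows moves held-out
probabilities by less than 0.05. The faPEA probability is the fraction of
trees voting faPEA. A note on $D'$: with $D' = D$ (no random subsetting)
trees would differ only through their bootstrap draws, contradicting the
intent of growing decorrelated trees; $\lfloor\sqrt{D}\rfloor$ is the
standard choice and `rf_config(predictors_per_node = )` exposes the
alternative. Baselines: logistic regression and polynomial-kernel SVMs of
degree 2 and 3, with features z-scored by training-fold statistics and the
minority class (faPEA) weighted 1.5; SVM probabilities come from Platt
calibration of the decision values.

Evaluation is 10-repeat, 10-fold cross-validation with patientwise
stratified partitions: patients (never segments) are dealt to folds,
class-wise, each to the fold currently holding the fewest segments of
that class — the strongest stratification the grouping constraint allows
(the tests require every fold's class mixture within 10 percentage points
of the global one). Se/Sp use the 0.5 probability threshold, the natural
majority-vote point under uniform priors; AUC is the rank-based
Mann–Whitney statistic (ties counted half, verified against exhaustive
pairwise comparison). BAC = (Se+Sp)/2 per fold. Folds whose test part
contains one class have undefined AUC; they are recorded as missing and
excluded from the median/IQR summaries, never imputed. Folds whose
*training* part is single-class are skipped and logged. All randomness
descends from one master seed (repeat r uses seed + r − 1; model fits use
a repeat-and-fold-derived seed).

Recursive feature selection retrains the forest after discarding the
least-important feature (impurity importance), one per step, from D
features down to 1, independently for every CV partition; a feature's
selection probability at size $N_f$ is the fraction of partitions whose
retained set of that size contains it. The time-window analysis restricts
the cohort to segments within $t_w$ minutes of PEA onset and re-runs the
cross-validation per window.

## The synthetic generator

Real faPEA/unPEA recordings are restricted, so the generator emulates the
structure the pipeline exploits, with ground truth attached (true R-peak
indices, true ICC waveform, drawn parameters):

- **ECG**: a train of Ricker (Mexican-hat) wavelets — an adequate QRS
  surrogate because every ECG feature in scope measures QRS-band energy,
  regularity or dispersion, not full PQRST morphology — at a per-patient
  heart rate with per-beat Gaussian RR jitter (default sd 10 ms), plus
  white noise (default 0.05 mV).
- **TI**: DC level (80 Ω) + slow baseline drift (200 m-ohm at 0.08 Hz) +
  respiration-like sinusoid (150 m-ohm at 0.3 Hz) + the ICC + white noise
  (5 m-ohm). The ICC ground truth is the harmonic model itself: 3
  harmonics with amplitudes $\propto 1/k$, random phase, and AR(1)
  coefficient modulation whose pole matches the smoother's prior
  $\exp(-\lambda/f_s)$ — so the recovery tests probe the estimator under
  its own model class at a controlled SNR, which is the fair test of the
  implementation (not of model misspecification).
- **Class contrasts** (defaults): faPEA 60–120 bpm, 0.8 mV, 80–120 ms
  QRS, 50 m-ohm ICC; unPEA 30–70 bpm, 0.3 mV, 120–200 ms QRS, 5 m-ohm
  ICC. These encode the documented direction of every contrast (more
  regular, larger, faster ECG and a stronger heartbeat-locked ICC in
  faPEA) at magnitudes chosen to be physiologically plausible (the ICC
  amplitude stays below the ~100 m-ohm ceiling observed with pad
  impedance circuitry). Patients are disjoint between classes; segments
  of a patient share patient-level draws with 10% segment-level jitter,
  so patientwise cross-validation is meaningful.

What passing tests on this cohort do **not** show: robustness to chest
compression artifacts (segments are compression-free by construction),
electrode motion artifacts beyond white noise, morphology-dependent QRS
detection failures, or device-specific TI transfer characteristics. The
clean separability of the default cohort (cross-validated AUC near 1) is
a property of the planted contrasts, not a claim about clinical
performance; the null-permutation check (median AUC ≈ 0.5) and the
impedance-channel-only cohort (ECG+ICC ≫ ECG-only) verify that the
discrimination comes from the signals, not from leakage.

## Numerical choices and degenerate inputs

- Segment lengths other than exactly 5 s after resampling are rejected,
  not padded or cropped — silent padding would bias spectral features.
- Resampling is polyphase rational with a delay-compensated FIR
  anti-aliasing filter; canonicalization is idempotent.
- Problem sizes in the tests (cohorts of 40 patients per class, ~4
  segments per patient; 50 segments for the recovery study) keep the full
  suite at a few minutes while leaving every estimate far from its
  decision boundary.
- All-zero ECG → no beats → ICC features 0 with `icc_available = FALSE`;
  all-zero ICC → log power at its $\ln 10^{-12}$ floor; constant inputs
  give zero entropy/IQR/SNEO. All 17 features are finite on every input
  the generator or the validator admits.
- The 10% bootstrap needs roughly 100+ training segments before trees can
  split at `min_leaf = 5`; far below that the forest degenerates to the
  prior (a property to keep in mind with toy cohorts, not a failure of
  the configuration at study scale).

## Known limitations

The detector-dependent ICC gate (≥ 2 beats) means a segment whose QRS
train defeats the detector contributes zero ICC features rather than an
estimate; the Welch cross-power window (1 s) trades frequency resolution
for stability on 5-s segments; and the generator's respiratory and wander
components are single sinusoids, milder than real ventilation artifacts.
The pipeline processes segments independently — it does not aggregate
evidence across a patient's segments into an episode-level prognosis.
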
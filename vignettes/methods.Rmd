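---
title: "Functional brain age from preterm EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional brain age from preterm EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neofba)
```

## The problem

In preterm infants with normal neurodevelopment, postmenstrual age (PMA, in
weeks) is taken as the true functional brain age (FBA). A regression model
trained to predict PMA from EEG therefore yields an FBA estimate for new
infants, and the *disparity* between predicted FBA and chronological PMA is
a biomarker of delayed or accelerated functional maturation; a disparity
beyond about two weeks is considered clinically meaningful. `neofba`
implements that estimator end to end, with the two stages that matter most
for a portable bedside tool — *channel* selection and *feature* selection —
as first-class, testable components.

## Signal model and preprocessing

Recordings are referential 12-electrode neonatal 10–20 EEG (Fp1, Fp2, T3,
T4, C3, C4, P3, P4, O1, O2, Cz, Pz). Preprocessing is, in order: 50 Hz
notch (second-order IIR, Q = 30; only the frequency is prescribed by
neonatal practice, the Q is this package's choice), resampling to 64 Hz,
fifth-order Butterworth band-pass 0.5–30 Hz, artifact suppression, and
segmentation into non-overlapping one-hour segments. The 16-channel bipolar
montage (double banana plus symmetric transverse pairs) is derived *after*
these per-electrode stages; all of them are linear, so they commute with
the electrode subtraction and the order is immaterial.

Numerical choices worth knowing:

* **Zero-phase filtering.** Skewness, kurtosis, envelope and burst timing
  are phase-sensitive, so filters are applied with exactly zero phase: the
  squared Butterworth/notch magnitude response (the classical
  forward–backward response) is applied in the frequency domain. This is
  identical to `filtfilt` up to boundary handling (circular rather than
  padded edges), and the package's fused preprocessing path is verified in
  the test suite to agree with the stage-by-stage path to 1e-10.
* **Resampling** is Fourier-method (spectrum truncation): exact output
  length `round(n * 64 / fs)` and an ideal anti-alias response. A 5 Hz
  sine resampled 500 to 64 Hz correlates with its analytic form above
  0.999.
* **Idempotence caveat.** With a 30 Hz band edge against a 32 Hz Nyquist,
  the band-pass transition band is unavoidably wide; repeated filtering is
  idempotent to well under 1% for passband content but *not* for broadband
  noise. Features are extracted from filtered content, so this does not
  propagate.
* **Artifact suppression** stands in for the artifact-subspace-
  reconstruction step used with clinical recordings, whose calibration
  internals are outside this package's scope: one-second windows are
  scored by a robust z-score of window RMS (median/MAD across the
  recording), windows above z = 5 are replaced by linear interpolation
  between the *median levels* of the flanking half-second of clean data,
  and a mask of repaired spans is returned. Medians, not raw flank
  samples, anchor the repair: a cubic spline through dense noisy anchors
  oscillates across the gap by more than the artifact it removes. Clean
  recordings pass through bit-identical.
* The beta band (13–30 Hz) abuts the Nyquist frequency after resampling to
  64 Hz; edge attenuation near 30 Hz is inherent to that design and is
  shared by all beta-band features.

## The 86-feature channel vector

Each one-hour channel is cut into 119 rectangular 60 s epochs with 50%
overlap. Per epoch and per band (delta 0.5–4, theta 4–7, alpha 7–13, beta
13–30 Hz, each extracted by a fifth-order zero-phase Butterworth):

* **Amplitude (6):** signal power (mean square), SD, skewness, kurtosis,
  and the mean and SD of the Hilbert-transform analytic envelope.
  Kurtosis uses the *excess* convention (normal = 0); downstream z-scoring
  makes the constant offset irrelevant.
* **Range-EEG (8):** peak-to-peak voltage over 2 s half-overlapping
  sub-segments, summarised by mean, median, 5th/95th percentile margins,
  width (upper − lower margin), SD, CV, and asymmetry
  `((upper − median) − (median − lower)) / width` — a bounded (±1)
  symmetry measure, recorded as missing when the width is zero.
* **Spectral (6):** from a Welch PSD (2 s Hamming windows, 50% overlap) of
  the broadband epoch, integrated over the band: band power, relative
  power (band / total 0.5–30 Hz), Wiener entropy (spectral flatness,
  geometric over arithmetic mean of the in-band PSD), Shannon entropy of
  the unit-sum in-band PSD (natural log), the mean squared difference
  between consecutive unit-sum short-time spectra, and the 95% spectral
  edge frequency computed *within* the band (band-resolved features are
  per-band throughout, so the SEF is band-relative too).

Broadband only: **inter-burst intervals (5)** — mean, median, SD
(population convention, so two bursts give SD 0 rather than an undefined
value), CV of the gaps between detected bursts, plus the burst ratio
(burst time / epoch length) — and the **Higuchi fractal dimension** with
`kmax = 6`, clipped to [1, 2].

Bursts are detected by an amplitude-envelope surrogate for the published
neonatal burst detector (whose internals live in its own reference): the
Hilbert envelope smoothed by a 0.5 s moving average is thresholded at
`min(1.5 × median envelope, 15 µV)`; supra-threshold runs of at least 1 s
are bursts and gaps under 0.5 s are merged. The absolute 15 µV arm exists
because a purely median-relative threshold can never classify sustained
high-amplitude activity as one long burst (the envelope never exceeds
1.5× its own median when it is constant); the floor encodes the field's
working definition of "high-amplitude" discontinuous activity, and all
four parameters are exposed in `burst_params()`.

That is 4 × (6 + 8 + 6) + 5 + 1 = **86 features per channel**, each the
average of its per-epoch values with missing epochs skipped; concatenating
channels gives 258 features for three channels and 1376 for the full
montage. For speed, band filtering and envelopes are computed once on the
full hour and then epoched — for these linear, time-invariant operations
this differs from per-epoch filtering only in boundary transients, and it
removes 119 per-epoch edge artifacts rather than adding them.

## Dataset assembly

Splitting is by *subject* (never by segment), 7:3 within integer-PMA-week
strata, so segments of one infant can never straddle the split; singleton
strata merge into their nearest neighbour. Features are z-scored with the
population-SD convention, with µ and σ estimated from training rows only
and frozen into every fitted object; constant columns map to zero.
Missing values are median-imputed, again with training-only medians.
Cross-validation folds are likewise grouped by subject and stratified by
PMA week. These three guards are what the anti-leakage tests assert:
deleting every test subject changes no training-derived artifact.

## Channel selection

Candidate channel subsets are scored by the grouped 5-fold cross-validated
MAE (in weeks) of a grid-searched SVR on the concatenated per-channel
features; no feature selection runs inside this loop. Searches:

* **FA / BE** — deterministic greedy growth/shrinkage, ties broken to the
  lowest added / highest removed channel ID.
* **BPSO** — binary particle swarm: bit-vector particles over the 16
  channels, Bernoulli(0.5) initial positions, Uniform(−1,1) velocities,
  the canonical inertia + cognitive + social velocity update, and the
  sigmoid transfer `x = 1 iff U(0,1) < 1/(1+e^{−v})`. The global best is
  the argmin-MAE personal best: a per-dimension "best bit" has no defined
  MAE, so the update is the canonical global-best form. All-zero particles
  are re-sampled. Every evaluated particle also updates a per-cardinality
  best-seen ledger.
* **bpso_fa_be** — BPSO's best subset seeds FA upward and BE downward; the
  three per-cardinality ledgers merge, keeping the minimum MAE at each
  cardinality 1..15. GA (fitness-proportional selection on 1/MAE, uniform
  crossover, bit mutation, one-elite carry-over) and SA (bit-flip
  Metropolis with geometric cooling) are drop-in baselines with the same
  expansion.

Subset evaluations are memoised by `(subset, fold seed, grid)`; the cache
changes runtime only, never results, and every search is reproducible from
its configuration and seed. Default swarm parameters follow the published
configuration (P = 100, w = 0.5, c1 = c2 = 1.5, L = 100); `fba_control()`
defaults to a compact swarm (16 particles, 12 iterations) sized for
cohorts of tens of subjects, where the full swarm would re-evaluate the
same few thousand reachable subsets many times over. Inside search loops
the SVR grid is the compact `wrapper_grid()` (5 candidates spanning the
same C range, linear + RBF); the full 198-candidate grid is reserved for
the final fit. Both are explicit arguments everywhere. Whether the
reported per-cardinality MAEs come from one merged ledger or separate
re-runs is an open design point; this package uses the merged ledger and
reports it as such.

## Feature selection

`pcc_rfe_svr` first removes redundancy: all feature pairs with |Pearson r|
> 0.9 are scanned in canonical column order and the *later* member of each
still-kept pair is dropped (the choice of victim is underdetermined;
canonical order makes it deterministic). The filter is unsupervised —
feature-against-feature only — so it cannot leak the label. RFE then
iteratively fits a *linear-kernel* SVR on the survivors (coefficient
magnitudes are only a meaningful importance ranking for a linear model,
whatever kernel the final predictor uses), records the grouped-CV MAE at
the current feature count, and removes the single lowest-|w| feature until
one remains. The optimum k\* is the curve's argmin, ties to the smaller k
(parsimony). `pcc_svr` (filter + nested univariate-R² curve — the curve
construction is this package's extension, since "SVR directly after
filtering" defines no ordering) and `rfe_svr` (no filter) are ablations.
Per-feature R² against PMA — the squared Pearson correlation — is reported
for the selected set.

## Models and evaluation

The final SVR is grid-searched over C ∈ {0.01, 0.11, …, 1.01}, gamma ∈
{scale, auto, 0.01, 0.1, 0.5, 1} and kernels {linear, RBF, polynomial}
(198 candidates, ties to the first in C-major order). The heuristics are
defined exactly as `scale = 1/(d·Var(X))` (population variance of all
entries) and `auto = 1/d`. Random forest and gradient-boosted trees
(xgboost; 500 trees / 150 rounds, depth 3, learning rate 0.1 — fixed,
seeded defaults, since the comparison of interest is relative ordering
rather than tuned tree performance) are alternative `fit_model()`
back-ends. A LightGBM back-end is not provided; with SVR, RF and GBDT
present, the model-comparison claim (SVR best) remains testable.

Evaluation reports MAE in weeks (Σ|Y − Ŷ|/K), the five error bins
(−∞,−2), [−2,−1), [−1,1], (1,2], (2,∞) with boundary ties assigned inward,
accuracies within ±1 and ±2 weeks, and per-PMA-group (28–30, 31–33, 34–37,
38–40 weeks) five-number summaries with 1.5 IQR outliers. Predictions are
per segment; `predict(fit, newdata, aggregate = "subject")` optionally
takes the within-subject median.

## The synthetic cohort

Clinical neonatal EEG is not publicly shareable, so the package carries a
generator that emulates the *maturational structure* such a cohort would
show, making every downstream stage testable. Per electrode, discontinuous
activity is an alternating renewal process with gamma-distributed (shape 2)
burst and inter-burst durations riding on 1/f^0.8 band-limited noise.
Four effect-size dials encode maturation per week of PMA above 28:

| parameter | default | meaning |
|---|---|---|
| `ibi_slope` | −0.35 s/wk | mean IBI 6 s at 28 wk shrinking to 1.8 s at 40 wk |
| `burst_ratio_slope` | +0.025 /wk | burst-time fraction 0.45 → 0.75 |
| `amplitude_slope` | −1 µV/wk | burst SD 30 µV → 18 µV |
| `delta_rel_power_slope` | −0.04 /wk | delta-band spectral emphasis 1 → 0.52 |

The defaults are chosen once to mirror the qualitative maturation
trajectories described for tracé discontinu — IBIs of several seconds at
very preterm ages shortening toward continuous activity at term, rising
burst ratio, falling amplitude, and a slow-activity emphasis that recedes
with age — at magnitudes large enough that one-hour recordings identify
them. PMA labels cover 28–40 weeks near-uniformly (weeks are cycled, then
jittered within the week); each subject is recorded once.

The age signal is injected only on the electrodes feeding the designated
informative channels (default IDs 6, 7, 9: Fp1-Fp2, Fp1-T3, Fp2-T4);
other electrodes get age-*independent* noise with matched marginal
variance (mid-range parameters). One consequence is deliberate and worth
stating: because bipolar channels are electrode differences, *every*
channel incident to an informative electrode carries some age signal —
with Fp1/Fp2/T3/T4 informative, channels 5, 8, 14, 15, 16 are partial
carriers too. The ground truth therefore records both the designated IDs
and the full carrier set, and recovery assertions on signal-level cohorts
check that selection stays inside the carrier set. For channel-*exclusive*
assertions (a selected subset must contain exactly the informative
channels) the package provides `synth_feature_table()`, which injects the
signal directly at the feature level and is exclusive by construction.
Its informative channels carry *complementary* shares of the label — the
standardised PMA is decomposed into per-channel latent components that sum
exactly to it — rather than redundant copies: with redundant copies,
dropping one informative channel is nearly free and "selection must
recover all of them" degenerates to a coin flip, whereas complementary
components give every designated channel (and every informative feature
within it) decisive marginal value, which is what recovery assertions
presuppose.

What passing tests on this cohort do **not** show: robustness to real
artifact regimes (movement, electrode pops, mains drift), sleep-state
cycling, inter-site montage dialects, or the true effect sizes of human
maturation — the generator's dials are free parameters, so synthetic MAEs
are not comparable to MAEs reported on clinical cohorts; only *recovery
behaviour* (does selection find the channels/features that carry the
signal; does the pipeline beat the mean predictor decisively) transfers.

## Problem sizes and determinism

The test suite and the acceptance script exercise the pipeline at a
desk-scale study condition: 40 subjects × 1 h at 250 Hz (the generator's
full-scale defaults mirror a clinical acquisition: 5.5 h at 500 Hz).
Exhaustive-search oracles run on 5-channel toy tables (31 subsets).
Every stochastic stage — generation, splitting, folds, BPSO/GA/SA — is
reproducible byte-for-byte from `(config, seed)`; caches and re-runs from
cached artifacts are verified to change nothing.

## Known limitations

* EDF support is deliberately minimal: 16-bit standard-header EDF with a
  uniform sampling rate; no EDF+ annotations, no proprietary formats.
* The ASR surrogate removes high-variance windows only; it does not
  reconstruct subspace components, and heavily contaminated recordings
  should be reviewed before trust is placed in the mask.
* The burst detector is an envelope-threshold surrogate, not the published
  neonatal detector it stands in for; IBI features on real data will
  differ in absolute terms from that detector's output.
* `fba()` assumes at least two subjects per (merged) PMA stratum and at
  least `folds` training subjects; cohorts of a handful of subjects should
  reduce `folds` in `fba_control()`.
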
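---
title: "Phase signatures of behavioral transitions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase signatures of behavioral transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phasesig` implements a population-coding analysis for hypothalamic
electrophysiology: discrete beta-band (15–30 Hz) oscillation episodes are
detected in the local field potential (LFP), spikes fired inside those
episodes receive an instantaneous (Hilbert) phase, per-unit behavioral
tuning is quantified by surrogate-based match scores, and a per-phase-bin
population statistic — the *phase signature* — feeds support-vector decoders
that classify upcoming versus current innate behaviors (feeding F, social
contact S, new-object exploration E) and transition versus control epochs.
Because real recordings are not bundled, the package ships a synthetic
session generator with known ground truth; every claim the test suite makes
is a parameter-recovery claim about that generator.

## The analysis chain

### Oscillation episodes

The LFP (1250 samples/s) is band-pass filtered (zero-phase Butterworth,
order 4 by default) and its amplitude envelope taken as the magnitude of the
analytic signal — full-wave rectification in the envelope sense — then
smoothed with a moving average of three cycles of the band center
(`smooth_window`, 0.133 s for beta). An episode is declared where the
smoothed envelope exceeds `mean + 2 s.d.` for at least 80 ms (25 ms for
gamma, 30–60 Hz), with boundaries extended outward to the `mean + 1 s.d.`
crossings and touching episodes merged.

Two estimation choices deserve explanation, because the thresholds are
nominal multiples of a "noise" mean and s.d. that can be measured on several
signals:

* **Baseline statistics are computed on the *unsmoothed* envelope.** The
  raw envelope of band-limited noise is approximately Rayleigh (mean
  ≈ 1.25 σ, s.d. ≈ 0.65 σ for band s.d. σ), so `mean + 2 s.d.` lands at
  ≈ 2.6 σ — a level genuine bursts clear and noise rarely sustains. Placing
  the same rule on the smoothed envelope (s.d. ≈ 0.3 σ) puts the threshold
  at ≈ 1.9 σ, which band-limited noise crosses for 80 ms many times per
  minute, flooding the detector with false events; measured on synthetic
  sessions this choice collapses precision to ≈ 0.15.
* **Boundary extension runs on the raw envelope** so episode edges are not
  blurred by the smoother; detected episode durations then average ≈ 205 ms
  for bursts whose envelope full width at half maximum (FWHM) is 202 ms,
  matching the duration scale such detectors report on real hypothalamic
  recordings.

Even so, an amplitude-threshold detector against a Gaussian 1/f background
has an irreducible false-positive floor: envelope excursions above
`mean + 2 s.d.` lasting 80 ms or more occur a handful of times per ten
minutes whatever the smoothing, which bounds achievable precision when true
bursts are sparse. The test suite states this honestly: at 20 injected
bursts per 10 min (SNR 4) recall exceeds 0.9 while precision plateaus near
0.8.

### Spike phases and histograms

Phase convention throughout: **0° at the band-passed signal peak, ±180° at
the trough** (the Hilbert phase of a cosine). Only spikes inside detected
episodes receive a phase (outside an episode the band phase is not
physically meaningful), taken from the nearest LFP sample — at 1250 Hz the
worst-case lookup error at 30 Hz is ≈ 4.3°, below every tolerance used.
Per-unit histograms use 20 bins of 18°, circularly convolved with a
Gaussian kernel of σ = 0.65 **bins** and normalized to sum to one. The
kernel width is a config knob (`kernel_sd_bins`); bins are the natural
scale on which 0.65 is a sensible smoothing s.d.

### Match scores

For each unit and behavior, the firing rate inside the behavior's scored
intervals is ranked against 1000 (desk default 200) surrogate rates obtained
by circularly shifting the behavior time stamps by uniform offsets of
120–240 s with random sign. Ties count one half, so the score is a mid-rank
percentile in [0, 1]: ≈ 1 marks behavior-activated units, ≈ 0 suppressed
ones, and for unmodulated units the score is uniform by construction (the
test suite checks Kolmogorov–Smirnov distance < 0.05 over 500 null cells).
Units need 20 spikes in the session to be scored (10 is the convention for
putative dopamine cells, selected by a strict < 10 Hz session rate; the
spike-width criterion requires waveforms and is out of scope).

### Phase signatures

Within an epoch set (for example all 2-s pre-onset transition windows),
each scored unit's smoothed phase histogram is computed from its in-episode
spikes (minimum 20), and for every phase bin the "highly active" cells are
the population upper quartile of the bin's firing probabilities — the top
⌈N/4⌉ units, ties broken by unit id (a warning marks fully tied bins). With
`c` the number of highly active cells whose match score exceeds 0.5 among
`N` selected, the signature is the odds

$$\varphi = \frac{c}{N - c},$$

clamped by half a count at the degenerate ends (`c = 0` or `c = N`) so φ
stays finite. φ is scale-free (match scores are percentiles) and strictly
increasing in `c`. The *peak:trough preference* is the mean φ over the 8
bins whose centers lie within ±72° of the peak divided by the mean over the
8 antipodal trough bins; values above 1 mark peak-concentrated behavioral
signaling (the transition regime), below 1 trough-concentrated signaling.

### Resampling constructions

Three resampling schemes coexist and serve different purposes:

* `bootstrap_signatures()` — the classical construction: each bin's active
  match-score multiset is resampled with replacement (1000× reference,
  200× desk default). Because φ is convex in `c`, the bootstrap mean sits
  slightly above the point estimate; the tests assert agreement with the
  exact binomial expectation rather than with the point value.
* `generate_control_epochs()` — control epoch sets placed by independent
  per-epoch circular offsets, rejecting any placement that overlaps a
  transition epoch (asserted exhaustively on every run). A per-set global
  offset was tried first and abandoned: with ~50 transition epochs covering
  a sixth of the session, a single feasible global shift essentially never
  exists. `run_pipeline()` additionally restricts controls to unscored
  time (`avoid =` the ethogram), the behavioral-state-matched variant:
  controls that overlap scored bouts sample units at behavior-gained rates,
  and histogram noise that scales as $1/\sqrt{n}$ then biases
  upper-quartile selection toward low-count units differently in the two
  classes — a rate confound that survives even full phase shuffling.
* `epoch_bootstrap_signatures()` — a case bootstrap over epochs (resample
  the epoch set with replacement, recompute histograms, reselect active
  cells, recompute φ). This is the transition-class row construction for
  the decoders, because its replicates carry the same epoch-sampling and
  cell-selection variability as the per-placement control rows; score-only
  bootstrap replicates are far tighter than across-placement signatures,
  and a support-vector machine will separate the classes on that variance
  signature alone. Within each replicate, units are subsampled to exactly
  `min_spikes` spikes (`equalize_counts`) so selection noise has equal
  variance for every unit.

### Decoders

Rows are φ replicates, features are (behavior × bin) φ values, classes are
balanced by seeded subsampling. The model layouts cover the standard
suite: one behavior and one peak-neighborhood bin (1 feature), all three
behaviors at one bin (3 features), three behaviors over the 8
peak-neighborhood bins (24 features), or all 20 bins when phase offsets
must be tolerated. Kernels follow the dimensionality rule: radial basis for
≤ 8 features, linear above (`svm_dim_cutoff`); the SVM cost stays at the
e1071 default of 1. Accuracy is estimated by stratified 10-fold
cross-validation, averaged within and then across repeats (1000× reference;
50 desk default, 10 for the per-bin model sweep). Significance uses
right-tailed label permutation, `p = (1 + #\{null ≥ observed\}) /
(1 + n_{perm})`, each permutation evaluated with a single
cross-validation (200 reference, 100 desk default).

The cross-bin protocol (`train_best_bin_test_others()`) trains on the bin
with the largest between-class signature-amplitude difference anywhere in
the cycle and tests on every peak-neighborhood bin except the training bin,
which a second decoder trained on the runner-up bin covers. Only structure
that generalizes across phase bins — genuine phase-specific coding — scores
highly.

`phase_shuffle()` is the phase-specificity null: every spike phase is
jittered by a uniform offset (default the **full circle**; one bin width is
available but leaves rotated-yet-intact structure a best-bin decoder can
still find) and all spikes of an epoch class are then rotated together by a
common random phase between 2.5 rad (the peak-neighborhood width) and π,
independently per class. Firing rates and epoch membership are untouched.

A caveat the package states plainly: even after a full phase shuffle, two
*finite* epoch pools remain weakly distinguishable, because active-cell
selection couples to each pool's incidental spike composition and the
histogram smoothing correlates that luck across neighboring bins. Decoding
one control placement against another — with no real difference of any
kind — already beats label-permutation chance at this data scale. The
original-vs-shuffled *contrast* is therefore large and stable (≈ 0.9
vs ≈ 0.5–0.65 cross-bin accuracy), but the shuffled decoder's permutation
p-value fluctuates around the 0.05 line from seed to seed rather than
sitting safely above it.

### Markov sequence analysis

`markov_order_analysis()` fits order-0 (marginal) and order-1 (conditional)
categorical models to the behavior-label sequence with additive 1/K
smoothing on a training split, and reports the held-out log-likelihood gain
per symbol; the first held-out symbol conditions on the last training
symbol so both models score identical symbol sets. Independent sequences
give ≈ 0 nats/symbol, a deterministic three-cycle gives ≈ log 3, and an
optional label-shuffle test calibrates significance.

## The synthetic session generator

`generator_config()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| session length | 600 s | a ten-minute free-choice session |
| LFP rate | 1250 Hz | the standard downsampled wide-band rate |
| bursts | 75 /min, 202 ms FWHM, 20 Hz, SNR 6 | ≈ 25 % beta occupancy; FWHM matches the ≈ 202 ms detected-episode duration; amplitude such that detected episodes retain ≥ 20 in-episode spikes per unit inside the transition windows |
| population | 120 cells: 20 % multimodal, 15 % per behavior specific, 35 % untuned | multimodal fraction matches the ≈ 19 % reported for the lateral hypothalamus; total on the scale of one chronic multi-shank session |
| rates | base 8 Hz, tuned gain 3× | typical hypothalamic rates and behavior modulation |
| phase coupling | κ = 2 entrained cells; trough-locked (μ = 180°) except when recruited to the peak (μ = 0°) | most cells lock to troughs; "transition cells" shift to peaks before behavior onsets |
| ethogram | uniform Markov chain, 8-s mean bouts, 3–8 s unscored gaps | gaps must exceed the 2-s transition window so pre-onset epochs lie in unscored time, and leave room for state-matched controls |

The generator's key design decision is that **the transition state is a
selective phase shift with no rate change**: inside the 2-s pre-onset
window of behavior *b*, exactly those cells with a rate gain for *b*
(multimodal cells always, specific cells before their own behavior) switch
their preferred phase from trough to peak, at unchanged firing rate. An
earlier variant that also applied an anticipatory rate gain was removed:
it made transition epochs separable from controls by rates alone, so the
phase shuffle could not null the decoder. Von Mises coupling applies only
inside oscillation episodes (elsewhere no phase exists), implemented by
thinning against the exact injected-carrier phase — for overlapping,
merged bursts the phase is the argument of the summed analytic carriers,
not any single burst's phase — with the in-episode candidate rate tilted by
$e^{\kappa}/I_0(\kappa)$ so thinning leaves mean rates unchanged. Burst
placement uses the expected count at the configured rate with uniformly
jittered durations (±10 %), keeping ground truth simple; overlapping bursts
are merged in the ground-truth episode table.

What the generator does **not** emulate: non-stationary baseline rates,
bursty (non-Poisson) spiking, moving electrodes, volume-conducted artifacts,
multi-animal kinematics, or any waveform information. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real recordings contain that structure.

## Numerical and testing choices

* All randomness derives from one user seed through named FNV-hashed
  substreams; identical seeds give byte-identical pipeline output (hashes
  of every written file are compared in the tests).
* Degenerate inputs are explicit: constant LFP → no episodes (never a
  division error); empty phase sets and absent behaviors → errors or `NA`s
  with messages; fully tied selection bins → deterministic unit-id order
  plus a warning.
* Desk-scale problem sizes (200 surrogates/bootstraps/control sets, 50/20
  CV repeats, 100–200 permutations, 10-minute sessions, 120 cells) keep a
  full pipeline run in the low minutes on one core; the reference-scale
  values (1000×) are plain arguments.
* Rayleigh-based uniformity checks run at moderate per-cell spike counts:
  at very large n the test detects the sub-percent phase-occupancy ripple
  of finite noisy bursts rather than anything about spike coupling.

## Known limitations

* Precision of episode detection against sparse, threshold-straddling
  bursts is bounded by the Rayleigh excursion statistics of the background
  (see above); the package reports recall/precision/Jaccard rather than
  pretending a cleaner operating point exists.
* The shuffled-decoder permutation p-value is a seed-level coin flip at
  desk scale (finite-pool identifiability); the accuracy contrast is the
  robust quantity.
* The waveform-width criterion for dopamine cells and all
  optogenetic, imaging and video-scoring procedures are out of scope.
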
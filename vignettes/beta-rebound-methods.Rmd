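---
title: "Methods: quantifying somatotopic attenuation of the sensorimotor beta rebound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying somatotopic attenuation of the sensorimotor beta rebound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betarebound)
```

## The scientific question

Peripheral somatosensory stimulation (for example, a brief electrical pulse
to the lower lip) evokes a stereotyped sequence in the EEG over perirolandic
cortex: an event-related desynchronization (ERD) of the mu (8–12 Hz) and
beta (13–30 Hz) rhythms roughly 200–400 ms after the stimulus, followed by an
event-related synchronization (ERS) — the *beta rebound* — beginning around
500 ms and lasting a few hundred milliseconds. The rebound indexes the
return-to-baseline stage of somatosensory processing, and it is attenuated
whenever the same cortical territory is engaged by a concurrent task.

This package implements an analysis chain for a specific use of that
phenomenon: if hearing a speech sound produced with the lips (a bilabial
such as /bi/) engages lip somatosensory cortex, then pairing lip stimulation
with bilabial sounds should attenuate the lip-evoked beta rebound more than
pairing it with dental sounds (/di/, articulated with the tongue), and the
attenuation should be specific to the beta band and lateralized to the left
hemisphere. The experimental design is a within-subject 2 × 2 factorial
(syllable: bilabial/dental × lip stimulation: present/absent), extended to
2 × 2 × 2 by the analysis windows (ERD vs ERS), with saccadic eye movements
as the response effector so that manual motor preparation cannot contaminate
the sensorimotor rhythms.

## Analysis chain

1. **Preprocessing.** Continuous EEG is band-passed 0.5–50 Hz (zero-phase
   4th-order Butterworth, forward–backward), decimated to 250 Hz after a
   20-order FIR anti-alias low-pass, and re-referenced to the common average
   of the EEG channels (EOG excluded). Epochs span `[-1.5, +2.5)` s around
   vowel onset — the half-open convention gives exactly 1000 samples at
   250 Hz — and each trial/channel is baseline-corrected by its mean over
   −1000 to −150 ms.
2. **Behavioral scoring.** The bipolar horizontal EOG difference
   (right − left canthus) is low-passed at 20 Hz; within a 3 s window from
   question onset, the first local extremum exceeding 1.5 window-SDs from
   the window mean, at a latency of at least 150 ms, is the response
   saccade. Its sign gives direction (positive → rightward); trials without
   such a peak, or with a saccade towards the wrong side, are discarded.
3. **Time–frequency decomposition.** Complex Morlet wavelets on a
   4–40 Hz grid in 0.5 Hz steps (73 rows), with the cycle count rising
   linearly from 3 cycles at 4 Hz to 20 cycles at 40 Hz. Kernels are
   L2-normalized, with Gaussian SD `n(f)/(2*pi*f)` seconds, truncated at
   ±5 SD. The event-related spectral perturbation of a channel is
   `ERSP(f,t) = 10*log10(mean_k |W_k(f,t)|^2 / P0(f))`, with the divisor
   `P0(f)` averaged over trials *and* baseline time points (−1000 to
   −150 ms); output spans −1000 to +1000 ms. Maps are averaged over a left
   region of interest (C1, C3, C5) and a right one (C2, C4, C6).
4. **Map-level statistics.** Per time–frequency point, the dental − bilabial
   contrast is tested with a paired t across subjects; the null is built by
   sign-flipping each subject's difference map (exhaustive enumeration when
   the requested permutation count reaches `2^n`, random sampling
   otherwise), with the two-tailed permutation p floored at
   `1/(n_perm + 1)`. Benjamini–Hochberg FDR at q = 0.01 corrects across all
   points.
5. **Band/window ANOVA.** Mean ERSP is extracted for mu (8–12 Hz) and beta
   (13–30 Hz) in the ERD window (200–400 ms) and the band's rebound window
   (mu: 400–600 ms; beta: 600–800 ms), per subject and condition, and
   analyzed with a within-subject 2 × 2 × 2 ANOVA
   (syllable × stimulation × window) per band. Post-hoc paired t-tests
   compare the syllables in the rebound window separately for stimulation
   and no-stimulation trials, Bonferroni-corrected (α = 0.025 for two
   comparisons). Reaction times enter the same engine as
   syllable × stimulation × question-polarity — the ANOVA is factor-label
   agnostic.

## The synthetic-data generator

No public recordings accompany this paradigm, so the package ships a
generator whose output carries exactly the statistical structure the
analysis assumes, making every stage testable end to end.

Each subject's continuous recording contains:

* **1/f background** on every channel: white spectra shaped with amplitude
  ∝ `1/sqrt(f)` (power ∝ 1/f, flattened below 0.5 Hz), 10 µV RMS by
  default — the standard broadband EEG background model.
* **Mu and beta rhythms** over the six central electrodes only, as two
  independent sources per hemisphere (left drives C1/C3/C5, right drives
  C2/C4/C6, with per-channel weights peaking at C3/C4). Each rhythm is
  band-limited Gaussian noise (mu 8–12 Hz, beta 13–27 Hz) rather than a
  sinusoid, because sensorimotor rhythms are broadband; a pure-sinusoid
  carrier is available (`carrier = "sinusoid"`) for tests that need exact
  windowed power ratios. Realizations are drawn fresh per trial, so the
  activity is induced (non-phase-locked), as real ERD/ERS is.
* **An event-locked gain profile** multiplying both rhythms: 1 in baseline,
  `erd_gain` (default 0.6) in 200–400 ms, `ers_gain` (default 1.5) in
  500–800 ms, with 50 ms raised-cosine ramps placed *outside* the windows so
  that within-window power equals the squared gain exactly. On bilabial +
  stimulation trials the beta rebound's excess gain is reduced by
  `rebound_attenuation`, scaled per channel by `left_lateralization`
  weights (1 on C1/C3/C5, 0 on the right, by default). The mu rhythm never
  carries a syllable effect, matching the empirical dissociation between
  the bands.
* **EOG saccades**: an antisymmetric boxcar deflection (60 µV across the
  two canthus electrodes, 300 ms hold) at question onset plus a log-normal
  latency (mean 530 ms, SD 90 ms), sped up 22 ms by stimulation and slowed
  49 ms for "no" answers; the executed side is flipped with probability
  0.131, mirroring the reported discard rate.

**Calibration.** Oscillator amplitudes (mu 2.5 µV, beta 1.5 µV RMS) were
chosen so that band power at the rhythm's frequency is comparable to the
1/f power inside the analysing wavelet's bandwidth; with the default gains
this puts group ERSP values in the ±0.5–2 dB range typical of sensorimotor
ERD/ERS, the same order as published group maps. The defaults were fixed
from this reasoning, not fitted to any reference output.

What the generator does *not* emulate: ocular and muscle artifacts, line
noise (beyond an optional flag), the 4 ms electrical stimulation artifact,
volume-conduction correlation structure beyond the shared hemispheric
sources, and non-stationarities such as drowsiness. Passing tests therefore
demonstrate the correctness and calibration of the analysis chain under its
own assumptions, not robustness to every failure mode of real recordings.

## Numerical choices

* **Wavelet edge handling.** An output time is considered edge-safe when at
  least ±3 Gaussian SDs of the kernel lie inside the epoch; the outermost
  tails (below 1% of peak amplitude) fall on zero padding. Requiring the
  full ±5 SD support would make −1000 ms unattainable at 4 Hz inside a
  `[-1.5, 2.5)` s epoch, while at ±3 SD the approximation error is far
  below the quantities of interest. Epochs genuinely too short raise an
  error naming the offending frequency.
* **Averaging order.** ERSP is computed per electrode and then averaged
  across ROI electrodes in dB. Averaging voltage before decomposition is a
  defensible alternative (the two differ for non-phase-locked activity);
  per-electrode averaging is the common ERSP practice and treats each
  electrode's baseline on its own footing.
* **Baseline divisor.** `P0(f)` uses the trial-average baseline power (not
  per-trial normalization), the standard ERSP definition; per-trial
  division changes the estimator's bias for low trial counts.
* **Saccade statistics.** The 1.5 SD threshold is computed from the trial's
  own 3 s window by default (`stats_scope = "window"`); whole-session
  statistics are available behind a flag. Both polarities are accepted and
  the first qualifying local extremum wins.
* **Permutation scheme.** The map contrast permutes at the subject level by
  sign-flipping paired differences — exchangeable under the null of no
  condition difference and consistent with group-level paired t maps. With
  12 subjects only 4096 sign patterns exist, so the implementation
  enumerates exhaustively whenever `n_perm >= 2^n` and samples otherwise;
  sampled p-values are floored at `1/(n_perm + 1)`. A consequence worth
  knowing: at n = 12 the exhaustive two-tailed floor is 2/4096, so
  point-wise FDR at q = 0.01 across a full 73 × 501 map can only reject
  when many hundreds of points sit at the floor simultaneously — the
  band/window ANOVA is therefore the primary inference for moderate
  effects, with the map masks serving as a conservative localizer.
  Trial-level label shuffling (which would lower the floor) is not offered:
  the chain aggregates to subject-condition maps before inference,
  matching group-level paired t statistics.
* **Baseline significance.** The bootstrap null for "different from
  baseline" redraws one baseline time point per trial, recomputes the map
  statistic, and thresholds at the two-tailed percentiles — a documented
  reconstruction of the usual bootstrap baseline test.
* **ANOVA engine.** Each effect's F is the squared paired t of the ±1
  contrast scores, algebraically identical to the full sums-of-squares
  within-subject decomposition for 2-level factors (both identities are
  enforced in the test suite to 1e−8).

## Problem sizes used by the test suite

The statistical calibration studies run at reduced scale, chosen as the
smallest sizes at which the checks are sharp:

* *Type-I calibration*: 200 null datasets of 12 subjects on a 96-point
  grid, 1000 permutations each; the empirical point-wise false-positive
  rate is compared with the attainable rate of the discrete permutation
  p-value at α = 0.01.
* *Parameter recovery*: 50 studies of 12 subjects × 48 trials (12 per
  syllable × stimulation cell) at 250 Hz with a 2.5–3.2 s inter-trial
  interval, a mu+beta-restricted wavelet grid (8–30 Hz, 2 Hz steps, same
  cycle ramp), full rebound abolition (`rebound_attenuation = 1`, the
  strong end of the reported phenomenon) and a clearly expressed 4 µV
  beta rhythm. Detection is the parametric interaction F test; the
  map-permutation stage is exercised separately. This scaled design was
  fixed after a design-phase power analysis and not adjusted afterwards.
* The full-scale conditions (12 × 192 trials, 73-row grid, 10000
  permutations) run once in `scripts/acceptance.R`.

## Known limitations

* The EDF and BrainVision readers/writers cover the common binary layouts
  (16-bit EDF+C with annotations; multiplexed IEEE-float/int-16
  BrainVision) and are not general-purpose format libraries.
* ICA-based artifact removal is out of scope (it is a manual step in
  practice); the pipeline assumes artifact-free input or synthetic data.
* Only integer decimation factors are supported for resampling.
* The right-hemisphere rebound in the generator matches the left in
  amplitude; empirically the ipsilateral rebound is weaker. This is
  conservative for the lateralization tests (any leakage of the left-ROI
  effect into the right ROI would be *easier* to detect against an equal
  baseline).
* With very small trial counts per cell the reaction-time ANOVA can lose a
  cell to behavioral discards; the pipeline then reports the EEG analyses
  and skips the RT table with a warning.
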
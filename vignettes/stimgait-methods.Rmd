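---
title: "Methods: models, generators and numerical choices in stimgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices in stimgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stimgait)
```

# Overview

stimgait implements a personalized deep-brain-stimulation (DBS)
optimization pipeline for gait in Parkinson's disease: a composite
Walking Performance Index (WPI) from spatiotemporal gait kinematics, a
Matérn-kernel Gaussian-process (GP) map from stimulation parameters
(amplitude mA, frequency Hz, pulse width μs) to WPI with a best/worst
proposal policy, gait-phase-locked spectral features from pallidal and
cortical field potentials, and mixed-effects biomarker regression.
Because the patient recordings this kind of study rests on are not
publicly deposited, every stage is validated against a first-class
synthetic cohort generator with complete ground truth.

# The Walking Performance Index

Four trial-level metrics enter the index: mean stride velocity (SV),
mean arm-swing amplitude (AS), and the coefficients of variation of step
length (VSL) and step time (VST). Within a visit each metric is min–max
scaled to [0, 1] across the visit's trials, and

$$\mathrm{WPI} = \tfrac{1}{4}\left(SV_{norm} + AS_{norm} +
  (1 - VSL_{norm}) + (1 - VST_{norm})\right),$$

so faster strides, larger arm swing and lower variability all raise the
index, with equal weights. Raw WPI lies in [0, 1] by construction. Each
trial is then divided by the visit's clinically-optimized trial (the
*baseline normalization*), putting all visits on a common "clinical = 1"
scale.

Two normalization choices were genuinely open and are fixed here:
per-visit min–max scaling (the minimal scheme delivering both the [0,1]
component range and "higher = better"), and the uninformative midpoint
0.5 for a metric that is constant across a visit, which avoids biasing
the composite in either direction. Variability uses the sample-SD
(ddof = 1) coefficient of variation, which is dimensionless and
comparable across walking speeds. A visit whose clinical trial scores a
raw WPI of exactly 0 cannot be baseline-normalized and is marked
unusable with a warning.

# Gait events, cycles and phases

Footswitch (force-sensitive resistor, FSR) channels drive event
detection: heel strike is the upward crossing of the heel channel at 10%
of its trial maximum with a 50 ms debounce; toe off is the downward
crossing of the last-active forefoot channel. The threshold fraction and
debounce are design choices (robust to baseline drift); the fallback
goniometer detector uses standard kinematic surrogates — dorsiflexion
maxima for heel strike, peak plantarflexion velocity for toe off — and
is flagged as approximate.

A left-referenced cycle is LHS → RTO → RHS → LTO → next LHS with
half-open phases DS1 (double support), CLS (contralateral swing), DS2
(double support after the contralateral swing) and ILS (ipsilateral
swing). The four phases partition the stride exactly. Cycles whose
cumulative pelvis-heading change exceeds 45° are flagged as turns and
excluded, mirroring a 6 m back-and-forth walkway; 200 steps are read as
100 gait cycles per reference side (a step being a half-stride).

# The GP model of stimulation response

The covariance between two settings is an anisotropic Matérn kernel
with smoothness ν = 3/2, which has the closed form
$(1 + \sqrt{3}r)\exp(-\sqrt{3}r)$ in the per-axis scaled distance $r$.
Inputs stay in raw physical units so the length scales (initialized at
1 mA, 20 Hz, 10 μs) keep physical meaning. Hyperparameters — three
length scales, a signal variance and an observation-noise variance — are
chosen by maximizing the log-marginal likelihood with L-BFGS-B in log
space using analytic gradients, restarted (default 40) from seeded
log-uniform initializations within bounds. Targets are centered before
fitting; far from data the posterior reverts to the target mean.

Proposals are pure exploitation in both tails: the posterior-mean argmax
("predicted best") and argmin ("predicted worst") over a device-realistic
grid (0.1 mA × 5 Hz × 10 μs), matching a protocol that tests the model's
best and worst predictions alongside the clinical setting at each visit.
Ties break toward lower amplitude, then lower frequency. Grid cells
within half a step of an already-tested setting are skipped when
proposing, so successive visits probe new ground; the final reported
model is refit on every observation. `initial_design()` supplies a
maximin Latin-hypercube set of probe settings for the pre-model visits.

# Synthetic cohorts

The generator emulates the statistical structure the analyses assume,
with every random draw tied to a derived seed.

**Response surfaces.** Each subject's unknown setting→WPI map is a
Gaussian bump over the neurologist-defined safe box, with the optimum in
the middle 80% of the box and per-axis widths of 40–80% of the box span
(gait responses to DBS parameters vary smoothly over tens of Hz and
tenths of mA, not as sharp resonances). WPI is expressed on the
baseline-normalized scale: baselines of 0.35–0.5 and peaks of 1.3–1.55,
matching the spread of per-subject WPI ranges reported across tested
settings (roughly 0.27–1.56). Surfaces are redrawn until the clinical
setting attains at least 35% of the subject's dynamic range, reflecting
months of clinical pre-optimization. Trial-level observation noise
defaults to SD 0.03.

**Visits.** Each visit tests the clinical setting plus uniformly drawn
probes, at least half of which are clearly worse than clinical and none
of which exceed a modest improvement over it — the situation a
best/worst testing protocol creates around a well-optimized clinical
setting. This keeps the clinical trial's raw WPI well inside the visit's
range, so baseline normalization stays well conditioned.

**Kinematics.** Ground-truth events carry stride-to-stride jitter whose
dispersion falls as true WPI rises; pelvis, wrist, footswitch,
goniometer, heading and chest-acceleration streams are built to invert
the index definitions, so the analysis pipeline recovers the trial's
planned metrics up to sampling noise. The wearable kinematic rate
defaults to 100 Hz (a configurable choice; published wearable rates
vary), the implanted device streams neural data at 500 Hz and its
accelerometer at 64 Hz on a clock offset by a configurable amount from
the wearable clock.

**Neural channels.** Each hemisphere provides one pallidal (GP) and two
cortical bipolar channels as 1/f background plus band oscillations
whose amplitude is gated on the gait-phase intervals. The beta carrier
is a bank of fixed tones spread across 14–26 Hz so every wavelet row in
the beta band carries signal; a shared carrier across GP and cortex
creates cortico-pallidal coherence structure. Phase-constant contrasts
(beta higher during stance phases) reproduce phase-locked spectrogram
structure.

**Biomarker slope calibration.** The generator's contract is that
regressing baseline-normalized WPI on the z-scored GP-beta phase feature
recovers the configured coefficients (defaults −0.22 for DS2, −0.23 for
ILS, in WPI units per z unit). Because the per-visit z-scoring fixes the
feature scale from the data itself, the slope and the feature–WPI
correlation cannot be chosen independently of the planned WPI spread;
the calibration solves, in closed form, for the planned per-phase slope
amplitude and trial-level noise that yield the target coefficient at a
feature–WPI correlation of 0.35 — the effect-size regime implied by a
reported |t| ≈ 3 at ~70 observations. The waveform realization then
attenuates planned contrasts (wavelet time-smearing over short phases,
carrier power fluctuations inside the pooled z scale, off-ridge row
dilution); the per-phase transfer fractions (0.40/0.50/0.36/0.49 for
DS1/CLS/DS2/ILS) and residual feature-noise SDs (0.14/0.11/0.25/0.13)
are fixed design constants of the generator, characterized against the
package's own extraction on reference cohorts and documented here.
Visits are planned jointly per subject so one global gain serves all
visits.

**Artifacts.** `inject_artifacts()` adds stimulation tones with
half-frequency subharmonics, 75–150 Hz bursts scaled to a requested z
level, a ~1.1 Hz cardiac-like spike train (kept below the gamma
threshold by default, and deliberately not removed by the pipeline), and
frozen-sample packet-loss runs, each recorded as ground-truth intervals.

What the generator does *not* emulate: medication state and washout,
freezing-of-gait or festination episodes, non-stationary background
spectra, and electrode-contact geometry. Passing tests therefore show
the pipeline's correctness and calibration on data with the assumed
statistical structure, not robustness to every clinical contingency.

# Neural preprocessing

Clock synchronization matches prominent acceleration peaks (mean + 2 SD,
0.4 s separation) between the chest wearable and the device
accelerometer by cross-correlating their impulse trains on a 64 Hz grid,
then averaging matched peak-pair offsets. The main high-pass is a 1 Hz
zero-phase Butterworth (order 4 — unstated in the underlying protocol,
chosen as the conventional default; forward–backward filtering doubles
the effective order and avoids phase distortion of event-locked
analyses). Gamma-range outliers are found on a detection path — 4 Hz
order-4 high-pass, 75–150 Hz band-pass, per-trial z-scores on the
band-passed series itself — flagged where |z| strictly exceeds 8,
dilated by a 200 ms blanking buffer on each side, merged and replaced by
NaN. Packet loss is operationalized as runs ≥ 50 ms of frozen or zero
samples (merged across < 50 ms gaps); this is an interpretation, as is
reading the 200 ms buffer as per-side. A cycle is excluded when packet
loss touches it at all or when more than half of any single phase is
blanked; z-scores are computed per trial (per-visit detection would also
be defensible and is configurable upstream of the mask).

# Spectral features

Scalograms use an analytic Morlet wavelet (ω₀ = 6) with unit peak
frequency-domain gain on a logarithmic grid of 10 voices per octave — a
portable stand-in for a generalized-Morse default, configurable.
Analysis spans 1–30 Hz; canonical bands are delta [2,4), theta [4,8),
alpha [8,12), beta [12,30), lower bound inclusive. Missing samples
propagate as missing columns with a cone-of-influence-style margin of
one wavelet e-folding time per frequency. Wavelet coherence smooths the
cross-spectrum over two cycles of each scale in time and 0.6 octave
across scales (conventional practice; the underlying protocol states
none), and is clipped to [0, 1]. Power and coherence are z-scored per
frequency within each visit, pooled over the visit's trials, separately
per hemisphere and site/pair; constant rows are zeroed and flagged. Band
averages are unweighted missing-aware means over grid rows; phase
features average non-missing samples within each phase interval (a phase
over half missing becomes missing) and per-trial features average usable
non-turn cycles.

# Statistical models

Per-subject: OLS of WPI on the four phase features of one
(site-or-pair, band) cell, plus a hemisphere indicator for bilateral
subjects, with Benjamini–Hochberg correction *within each model's four
phase p-values*. Group level: `wpi ~ feature + hemisphere +
(1 | subject)` fit by REML for estimates, with Wald t on residual
degrees of freedom (n − number of fixed effects, mirroring "t(66)"-style
reporting; Satterthwaite is deliberately not used), and a
likelihood-ratio test against the null model with both models refit by
maximum likelihood. Singular random-effect fits fall back to OLS with a
flag. The hemisphere-interaction check reports ΔAIC (interaction minus
main, ML fits) and the interaction Wald p. Backward elimination drops
the least significant fixed effect by LRT at α = 0.05 until all remain
significant. Residual diagnostics report Shapiro–Wilk p, sample
skewness and Pearson (non-excess) kurtosis with thresholds 0.39 and
3.6. The feedback model regresses feedback ranks on WPI ranks with a
subject random intercept; rank 1 is best on both scales. The group-level
BH family spans the tested feature set (per-subject families stay within
each model); both family definitions can be reproduced by adjusting the
relevant p-value column.

# Problem sizes and simulation scales

Validation uses scales chosen for a single-CPU workstation run:
biomarker-recovery cohorts of 3 subjects × 3 visits × 5 settings with
20 strides per trial (≈75 hemisphere-observations, the reported ~70
scale) over 12 seeds; optimizer recovery over 100 seeded surfaces
with budget 15 and 12 optimizer restarts per fit (the 40-restart default
applies to single fits); calibration simulations (FDR, type-I error)
over 500 feature-level replicates; and artifact/sync checks over tens of
trials. Waveform trials for spectral validation restrict extraction to
the pallidal channel and the beta band. The full-scale study condition
(100 strides per side, all sites/pairs/bands) is available through the
same functions.

# Known limitations

* The generator's biomarker contract is calibrated through fixed
  transfer constants; configurations far from the reference (very short
  trials, other bands, strong extra artifacts) will realize slopes with
  more bias than the documented regime.
* Pooled cross-visit correlations between baseline-normalized WPI and
  the latent truth are intrinsically limited by per-visit normalization;
  fidelity should be judged within visits.
* Pure-exploitation proposals with a 15-evaluation budget localize the
  optimum only to within a few per cent of peak performance on broad
  surfaces; the information in so few noisy trials bounds what any
  acquisition rule of this form can achieve.
* Event detection assumes footswitch polarity and loading patterns of
  forward walking; no automated correction replaces the visual
  inspection a clinical protocol would include.
* Likelihood-ratio tests on mixed-model fixed effects run slightly
  anti-conservative at the three-subject study scale (~6–7% rejections
  at a nominal 5%), a known few-cluster property of the chi-square
  reference; the test is calibrated once cluster counts reach the
  asymptotic regime.
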
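---
title: "Quantifying stimulation effects on speech and swallowing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulation effects on speech and swallowing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oromotorquant)
```

oromotorquant quantifies how a two-condition intervention — typically deep-brain
stimulation OFF versus ON — changes oromotor function, from four kinds of raw
recordings: single-word audio, facial/laryngeal EMG, facial-landmark
trajectories from markerless pose estimation, and videofluoroscopic swallow
studies. This vignette explains each metric's model and assumptions, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## Speech intensity

Each word is decomposed into a short-time spectrogram (25 ms Hann window,
5 ms hop, band 50–10000 Hz) and summarised per frame as total in-band power
in dB. A length-3 running median removes single-frame glitches, and the
trial's intensity is the median of the smoothed trace. The dB reference is
1.0: because only condition *differences* are interpreted, the reference
cancels and no SPL calibration is attempted. The median is taken over all
frames, not voiced frames only; for single words cut tightly around speech
the difference is small, and the choice is recorded here as an assumption.

Changes between conditions are classified into clinically banded categories:
above +5 dB a *large increase* (roughly the difference between quiet and
conversational speech), 0 to +5 dB an *increase*, 0 to −5 dB a *decrease*,
at or below −5 dB a *large decrease*. The +5 dB band edge is inclusive
downward (a +5.0 dB change is an *increase*).

`classify_intensity_change(c(-6, 2, 7))` →
`r paste(as.character(classify_intensity_change(c(-6, 2, 7))), collapse = ", ")`.

## Pitch, pulses and voice breaks

Voice breaks — interruptions of phonation — are counted from a glottal pulse
train. The pitch tracker is a filtered-autocorrelation design: the signal is
low-pass filtered at the pitch ceiling (zero-phase Butterworth), then each
40 ms Hann-windowed frame (three periods of the 75 Hz floor, 10 ms hop) is
autocorrelated and normalized both by lag zero and by the window's own
autocorrelation. Two design points deserve explanation:

* **The lag search extends above the ceiling.** A tone above the search
  ceiling (say 500 Hz with a 75–400 Hz range) has autocorrelation peaks at
  *multiples* of its period that fall inside the legal lag range; a naive
  tracker would report it voiced at half its true frequency. The tracker
  therefore searches down to a third of the ceiling's period and takes the
  *shortest* lag whose local maximum reaches 90% of the global maximum; if
  the implied f0 is above the ceiling the frame is unvoiced.
* **Voicing requires raw-signal periodicity too.** Low-pass-filtered noise
  is correlated at pitch-period lags, so the prefiltered autocorrelation
  alone over-reports voicing on aperiodic signals. The voicing strength is
  the minimum of the prefiltered and the raw-frame normalized
  autocorrelation at the chosen lag, compared against the 0.25 threshold
  (a deliberately permissive value, suited to irregular phonation).

Pulses are then placed at the absolute-amplitude peak inside successive
one-period windows advanced pulse-to-pulse within each voiced run. Candidate
peaks below 45% of the running median pulse amplitude, or below 10% of the
recording's global peak, are rejected: a freely decaying vocal-tract
resonance falls below half its per-period peak within half a period for any
bandwidth above ~55 Hz, so these gates separate true excitation from decay
tails and silence without an absolute calibration. A voice break is an
inter-pulse interval *strictly* longer than 16.67 ms (1.25 periods of the
75 Hz floor), counted only between the first and last voiced frame.

No parity with any external pitch program is claimed; the contract is the
one the tests enforce: sub-1% median f0 error across 80–350 Hz, unvoiced
majorities for noise and above-ceiling tones, and exact break counts on
stimuli with known gaps.

## Smoothed cepstral peak prominence (CPPS)

CPPS measures how far the cepstral peak produced by periodic voicing stands
above the overall cepstral trend; it falls with breathiness, noise and
jitter, and is the package's phonatory-quality metric. Per 48 ms frame
(2 ms hop) the log power spectrum is inverse-transformed to a cepstrum in
dB; the cepstrogram is then smoothed by moving averages across time (20 ms)
and quefrency (0.5 ms). Per frame, a straight line is fitted by ordinary
least squares over quefrencies 1–13.3 ms, and the prominence is the peak in
the 2.5–13.3 ms search band (the period range of the pitch search) minus
the trend at the peak. CPPS is the mean prominence across frames.

The absolute value depends on these windowing choices, so no numeric parity
with other implementations is claimed; the enforced contract is
*comparative*: monotone degradation with SNR, sensitivity to jitter,
amplitude invariance, and bitwise determinism. CPPS is computed over all
frames (not voiced frames only), recorded here as an assumption. The OLS
trend (rather than a robust line) is a simplicity choice; it is the
documented switch point if heavy-tailed cepstra ever warrant it.

## LPC formant estimation

Vowel articulation is quantified by the first two formants, estimated per
vowel interval with linear predictive coding:

1. pre-emphasis \(P(z) = 1 - 0.63\,z^{-1}\);
2. 15 ms Hamming frames with 80% overlap;
3. autocorrelation-method LPC of order \(\mathrm{round}(F_s/1000) + 2\)
   via Levinson–Durbin (guaranteed-stable, so every root maps to a
   well-defined bandwidth);
4. polynomial roots → frequency from the root angle, bandwidth
   \(-\tfrac{F_s}{\pi}\ln|z|\) from the radius;
5. keep roots with frequency > 90 Hz and bandwidth < 400 Hz; the first four
   by ascending frequency are F1–F4.

Per vowel, the F1 and F2 sequences are median-filtered (window 3 — the
smallest window that removes single-frame outliers), resampled by natural
cubic spline to 100 points over the vowel, truncated to points 15–85
inclusive (71 points, the stable ~70% around the vowel centre, avoiding
onset/offset transitions), and averaged. "Points 15 to 85" is read as
inclusive; the alternative 70-point reading would change means negligibly
but the count contract (71) is fixed and tested. The condition contrast is
the percent change of the ON mean relative to the OFF mean per formant.

Frames whose Levinson recursion degenerates are marked missing and dropped
before smoothing; a vowel with fewer than four usable frames yields a
missing summary rather than an unstable one.

## EMG: evoked potentials and voluntary envelopes

Motor-evoked-potential size is the area under the stimulation-triggered
average: per muscle, trials aligned to each trigger are rectified, averaged,
and integrated (trapezoid) over 10–75 ms post-trigger. Rectification
precedes averaging because the AUC of a signed average can cancel to zero
for polyphasic responses; the signed variant remains available via
`rectify = FALSE`.

Voluntary activation uses the standard envelope: zero-phase second-order
Butterworth bandpass 60–500 Hz, full-wave rectification, zero-phase
second-order low-pass at 6 Hz, floored at zero. The rectification step
sits between the filters by necessity: a 6 Hz low-pass applied directly to
a 60–500 Hz band signal is essentially zero, so an envelope reading is the
only one that makes an AUC meaningful. Zero-phase filtering keeps envelope
timing aligned with behaviorally defined movement windows. Per-event AUCs
are z-scored against the OFF-condition distribution of the same muscle;
fewer than two OFF trials, or (numerically) zero OFF variance, flags z as
undefined rather than producing infinities.

## Kinematics and swallowing

Movement amplitude is the maximum Euclidean excursion from the event's
first-frame position — tasks alternate neutral and expression, so the onset
position is the natural baseline (peak-to-peak is available as a documented
switch). Mean velocity is the mean framewise displacement times the frame
rate. Mouth aperture is the absolute shoelace area of 3 (profile view) or 4
(frontal view) landmark vertices per frame. Landmarks with pose-estimation
likelihood below 0.6 are linearly interpolated. Movement events are
expected to be identified manually; the optional automatic segmenter
(smoothed speed above 10% of its peak, 3-frame hysteresis, minimum event
length 5 frames) exists to make closed-loop testing possible and reproduces
constructed events within ±2 frames.

Swallow duration is the frame span from first barium appearance to swallow
completion divided by the frame rate (30 fps); residue is the labelled ROI
pixel area normalized by the full frame's pixel area, reported per region
and in total (an empty region set is a legitimate zero). Duration and
residue are compared OFF vs ON with a one-tailed paired t across
bolus-matched trials, because bolus volume and consistency dominate
between-trial variance.

## Inference

All mean comparisons use a percentile bootstrap: resample each group with
replacement preserving its size, record the difference of resampled means,
repeat 10,000 times, and form two-tailed percentile intervals at
α ∈ {0.05, 0.01, 0.001}; the null is rejected when 0 lies outside the
interval, starred as `*`, `**`, `***`. The percentile method (rather than
BCa or studentized intervals) matches this decision rule directly. Results
are bit-reproducible from the seed, and the caller's RNG state is left
untouched. Bonferroni correction divides α by the number of pairwise
comparisons in a family; families are supplied by the caller, since which
comparisons share a family is an analysis-level decision. A classic paired
t is the default paired test, with a sign-flip permutation alternative
(`method = "permutation"`). Pooled metrics are normalized as percent change
against the OFF-condition median.

```{r bootstrap-example}
set.seed(1)
b <- bootstrap_diff_means(rnorm(30, 0.8), rnorm(30), seed = 42)
tidy(b)
```

## The synthetic-data generator

Every analysis is exercised end-to-end on synthetic data with known ground
truth; the generator is first-class, tested code.

**Vowels** are source-filter synthesized: a glottal impulse train drives a
*cascade* of second-order resonators — a cascade, not a parallel bank,
because it yields an exactly all-pole spectrum, making LPC formant recovery
a well-posed estimation problem rather than a model-mismatch exercise.
Defaults: f0 120 Hz, formants 700/1200/2600/3500 Hz with bandwidths
80/90/120/150 Hz (an open central vowel), duration 0.5 s, RMS −20 dB re
full scale, rate 16 kHz (which puts the LPC order at 18, comfortably
covering four formants). Two forms of pitch variability are built in
because perfectly flat f0 is not phonatory-realistic and makes
spectrum-sampling artifacts coherent: a 4% linear intra-vowel declination
(nominal f0 stays the median), and — in two-condition datasets — per-trial
f0 drawn uniformly within ±8% of the base, emulating session-level pitch
drift across repetitions. The uniform draw matters quantitatively: LPC
formant estimates carry a small bias oscillating with the alignment of
harmonics and resonance (period ≈ f0²/F1 in f0), and uniform coverage of
one alignment cycle averages it equally in both conditions, keeping
injected formant effects recoverable.

**Voice breaks** are inserted with pause semantics: at a requested gap the
next pulse is delayed so the inter-pulse interval equals exactly
`max(period, floor(gap × rate)) / rate`, and the span between the bounding
pulses is zeroed with 5 ms cosine ramps (no clicks that would confound
voicing). Because pulse positions are integer samples, the number of
qualifying breaks is known exactly by construction — including the boundary
case of a gap equal to the 16.67 ms threshold, whose floor-quantized
interval falls just *below* threshold and therefore must not be counted.

**Words** wrap a vowel with band-limited noise-burst "consonants" and emit
an exactly aligned phoneme TextGrid. **Two-condition datasets** apply
effects (level shift in dB, percent formant shifts, gap insertion/removal,
SNR or jitter replacement) to the ON condition on top of natural per-trial
variability (f0 as above, 1% formant jitter, 0.5 dB level jitter), with a
truth table recording every injected effect and per-trial derived seeds.
**EMG** is a 60–500 Hz noise carrier amplitude-modulated by Hann burst
envelopes over baseline noise; **MEPs** are Gaussian bumps at fixed latency
after each trigger (closed-form AUC available); **trajectories** are
one-period sinusoidal displacements separated by rest, with events starting
on the neutral frame so baseline-referenced amplitude equals the programmed
displacement.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: natural glottal pulse shapes and spectral tilt,
formant transitions and coarticulation, nasality (spectral zeros, which
violate the all-pole assumption), room acoustics and recording-chain
coloration, EMG cross-talk between muscles, pose-estimation outliers beyond
i.i.d. jitter, and any pathology-specific structure beyond the controlled
effects. Results on patient recordings additionally depend on forced-
alignment quality, which is out of scope (TextGrids are consumed, not
produced).

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
whole stack is exercised in minutes on one core: a 32-point vowel grid
(F1 ∈ {300, 500, 700, 900} × F2 ∈ {900, 1200, 1800, 2200} × f0 ∈ {100,
150} Hz) for formant recovery; 50 seeded stimuli with six gaps each for
break exactness; 10 seeds × 5 SNR levels for CPPS ordering; 1000 null
experiments (n = 30 per group, 10,000 resamples each) for bootstrap
type-I error and coverage; 20 trials per condition for closed-loop effect
recovery. FFT lengths are the next power of two above the window; framewise
loops are vectorised where the profile warranted it. Tie-breaks and
degenerate inputs are resolved explicitly: even-length medians never arise
(windows are odd), all-silent segmentations return empty results rather
than errors, zero-variance paired differences flag the test degenerate, and
colinear aperture vertices give area zero.

## Known limitations

* Pitch tracking has no octave-cost dynamic programming; synthetic stimuli
  without octave ambiguity do not need it, but pathological voices with
  strong subharmonics might.
* CPPS and intensity absolute values are implementation-specific; only
  within-package comparisons are meaningful.
* The formant pipeline assumes an all-pole vocal tract; nasalized vowels
  break that assumption.
* Listener-consensus matching uses a 0.05 s timing tolerance ("exact same
  timing" is unworkable for free listening); the tolerance is configurable.
* The bootstrap assumes exchangeable trials within condition; repeated
  words within a session violate independence mildly, which is why per-word
  comparisons are offered alongside pooled ones.
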
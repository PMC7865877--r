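---
title: "ecgflow: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecgflow: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgflow)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what a passing test suite does and does not
establish.  No empirical claim here goes beyond what the tests and
`scripts/acceptance.R` themselves compute.

## The setting

A thumb-electrode home recorder produces a single Lead-I-equivalent ECG at
125 Hz, in millivolts, 20 s to a few minutes long.  Such signals carry two
characteristic distortions — high-frequency interference (mains, EMG) and
low-frequency baseline wander from movement — and one characteristic user
error, swapped electrode polarity, which inverts the waveform.  `ecgflow`
implements the analysis path such a device needs: cleaning, beat
delineation and interval measurement, multilabel rhythm classification, and
a rule-based health score with alerting.

## Signal quality

**High-frequency chain.** An order-4 Butterworth low-pass at 50 Hz joined
with a second-order IIR notch at 60 Hz (quality factor 30).  Both stages run
forward–backward, so the chain is zero-phase: on synthetic records the QRS
apex moves by at most 2 samples (16 ms), which the suite asserts.  With
125 Hz sampling the 60 Hz notch sits close to the 62.5 Hz Nyquist frequency;
the RBJ biquad design keeps an exact null at 60 Hz there.  If a record's
rate puts the notch at or above Nyquist the stage is skipped with a warning
rather than failing.

**Baseline chain.** An order-2 Butterworth high-pass at 0.67 Hz followed by
subtraction of a centred 1.0 s moving-average baseline estimate.  The moving
average is deliberately long relative to the QRS complex (~100 ms), so the
sharp deflections survive; its side effect is a small beat-synchronous
ripple (≈0.02–0.05 mV) in the output baseline, which the delineator must
tolerate (see below).  The order of the two chains is configurable
(`baseline_first`, default `TRUE`).

**Filter design in-package.** The runtime provides no filter-design library,
so Butterworth pole placement, the bilinear transform and the notch biquad
are implemented here; the coefficients were cross-checked against an
independent reference implementation during development, and the shipped
tests pin the behaviour spectrally (≥ 20 dB at 60 Hz, ≤ 5% distortion at
5 Hz, ≥ 90% suppression of a 0.2 Hz tone).

**Lead-off detection.** A record is "empty" when any contiguous 2 s window
has a sample standard deviation below 0.01 mV.  The thresholds are package
choices (no numeric criterion exists to reproduce): 0.01 mV is well below
any physiological beat-to-beat variation but above ADC noise at typical
gains, and 2 s is short enough to catch a lead drop mid-recording.

## Delineation and measurements

**QRS detection** follows the Pan–Tompkins recipe: 5–15 Hz band-pass,
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise thresholds with a 200 ms refractory period, and a search-back
pass that reconsiders sub-threshold candidates inside RR gaps longer than
1.66 × the median RR.  Detections are refined to the extremum of the
cleaned signal within ±100 ms, using the absolute amplitude so reversed
records are handled symmetrically.

**Boundary placement.** Wave onsets/offsets use a two-stage rule. A walk
away from the peak stops where the absolute slope stays below 10% of the
wave's own maximum slope; the reference slope is measured only near the
wave so a neighbouring deflection cannot inflate it, and the stop test uses
a 3-sample mean to ride over single-sample ripple.  Because the
moving-average baseline ripple can still delay that stop by a sample or
two, a second stage walks back toward the peak while the amplitude stays
within 0.02 mV of the boundary level.  When two waves genuinely merge (ST
segment vanishing at high rates), there is no quiet stretch to find; the
boundary is then placed at the flattest point of the transition, which is
the standard convention.  QRS boundaries are anchored at the Q and S
troughs when those are at least 0.02 mV deep, and fall back to the R peak
otherwise.

**P and T search windows.** T: from 20 ms after the QRS offset to 60% of
the RR toward the next beat.  P: 240–40 ms before the QRS onset, clipped to
start after the previous beat's T offset.  A P candidate must rise at least
0.08 mV above the window's own baseline (estimated from the window edges);
typical Lead-I P waves are 0.1–0.2 mV, while atrial-fibrillation
undulations are a factor of two to three smaller, so this threshold is what
lets the package report *absent* P waves on fibrillation-like records
rather than fabricating fiducials.

**Measurements.** All eight quantities are index differences times
1000/sampling rate: P duration, PR (P onset → QRS onset), QRS, QT (QRS
onset → T offset), QTc, T duration, atrial rate (from PP intervals, absent
when P waves are absent), ventricular rate (60 / mean RR).  QTc defaults to
Bazett (`QT/√RR`, RR in seconds, the most common clinical convention) with
Fridericia available.  Per-beat values are summarised by the median
(configurable to mean); the median is robust to the occasional mis-placed
boundary.  At 125 Hz one sample is 8 ms, which bounds the achievable
per-fiducial precision; the acceptance criterion (±20 ms on per-recording
medians) sits at 2.5 samples.

## The diagnosis network

Architecture, as introspectable from `build_network()`:

- the recording is split into non-overlapping segments (default 1280
  samples = 10.24 s; any multiple of 256 works) with zero padding of the
  final partial segment;
- 32 one-dimensional convolutions (kernel 16) in 8 stages of 4, every two
  convolutions wrapped into a residual block; the first convolution of each
  stage has stride 2 and the shortcut then max-pools by 2, so a segment's
  temporal length shrinks by 2⁸ = 256 before global average pooling;
- filters double every two stages (defaults 32,32,64,64,128,128,256,256);
- each convolution is preceded by batch-norm → ReLU → dropout
  (pre-activation ordering, dropout 0.2 by default);
- shortcuts project with a 1×1 convolution when channel counts change
  (entering stages 1, 3, 5, 7) — these projections are bookkeeping, not
  counted among the 32 layers;
- a single unidirectional GRU (hidden 64) consumes the per-segment
  embeddings in order; its final state feeds a dense layer with one sigmoid
  output per class, 20 for diagnosis, 1 for the reverse-lead detector
  (convention: 1 = reversed).

The loss is the mean per-class binary cross-entropy — the task is
multilabel, several items may hold at once — optimised with Adam
(lr 10⁻³ default, batch 16).  Everything (im2col convolutions on BLAS
`%*%`, batch-norm, GRU backprop, Adam) is implemented in the package; the
gradients were verified against central finite differences during
development, and the suite pins determinism (identical loss traces for
identical seeds) and an overfit sanity check.

**Prior-probability bias initialisation.** With 20 heads on one trunk, the
many always-negative classes exert a constant early gradient through the
shared GRU state; empirically this saturates the tanh state before the
informative classes learn anything.  `train_network()` therefore
initialises each output bias to the logit of its class base rate, the
standard remedy — after which the easy classes are already satisfied at
step 0 and the trunk trains on the discriminative signal.

**Scale.** Training on clinical corpora is out of scope; the network trains
and evaluates on the synthetic generator.  Tests run a reduced width
(base_filters 4, GRU 8, 256-sample segments) because polarity and
rate-class discrimination are width-independent at these signal-to-noise
ratios; the architecture checks run at the full default width.

## Health score and alerts

Each diagnostic item carries a risk category and a critical value
(deduction): nothing for sinus rhythm; 2–5 for sinus abnormalities; 9–15
for bundle-branch blocks and premature beats; 16–25 for pre-excitation,
escape beats, first/second-degree block, flutter and fibrillation; 50 for
the ventricular/supraventricular tachycardias and third-degree block.  The
score is `max(0, 100 − Σ deductions)` over detected items.  Choices the
rule set does not pin down, decided here: multiple detections **sum** (a
`max` mode is available); the score floors at 0; co-detected sinus rhythm
contributes 0; "lower than" is strict.  Alerts: rule 1 fires when the last
two scores are both < 85; rule 2 when ≥ 3 of the most recent min(5, n)
scores are < 90 (with fewer than 3 measurements it cannot fire); rule 1
wins when both fire; no post-alert reset is applied.  The boundary
behaviour ([85, 84] does not fire, [84, 84] does) is asserted exhaustively.

## The synthetic generator

Each beat is a sum of Gaussian deflections with analytic fiducials (onset =
peak − width/2, offset = peak + width/2, σ = width/6).  Defaults: P 0.15 mV
/ 80 ms, Q −0.10 / 30, R 1.0 / 40, S −0.15 / 30, T 0.30 / 160; PR 160 ms;
QT 360 ms.  Rate adaptation keeps the morphology physiological across
40–180 bpm: QT scales with √RR (Bazett inverted, capped at RR 1.2 s), the T
duration shrinks proportionally with QT, and PR compresses moderately
(factor 0.6 + 0.4·RR, RR ≤ 1 s) — without this, waves of adjacent beats
would overlap at tachycardic rates, which real hearts avoid the same way.

Rhythm classes and their label mapping: normal sinus (RR jitter σ = 2%) →
SN; sinus tachycardia/bradycardia (defaults 130/50 bpm) → SNT/SNB; sinus
arrhythmia (12% sinusoidal RR modulation at the respiratory 0.25 Hz) → SNA;
fibrillation-like (i.i.d. log-normal RR, CV 0.2, no P waves, 0.03 mV 6 Hz
undulation) → AF; premature ventricular/atrial beats (~10% of beats at 0.65
RR with compensatory pause; ventricular ones wide, P-less, higher
amplitude) → PVC/PAC; long-PR (240 ms) → AVBI; wide-QRS (doubled QRS
widths) → LBBB.  Only these 9 of the 20 items are credibly synthesizable
with this morphology model; the remaining 11 (PJC, VT, SVT, AFL, WPW, VE,
AE, JE, AVBII, AVBIII) are out of the generator's scope and the package
makes no claim about them beyond scoring rules.

Artifacts are additive: band-limited (≥ 40 Hz) Gaussian noise of specified
RMS and a baseline sinusoid of specified amplitude/frequency.  Reversal
negates the whole waveform.  All randomness derives from the spec's seed;
identical specs produce bit-identical samples.

**What a green test establishes — and what it does not.** The generator
emulates beat timing, gross P/QRS/T morphology, polarity, drift and
wide-band noise.  It does not emulate electrode motion artifacts, muscle
noise bursts, ectopic morphology diversity, ST-segment pathology, or
inter-patient variability.  Delineation recovery and classifier accuracy on
this substrate demonstrate internal consistency and algorithmic
correctness, not clinical performance; published clinical figures are
context, not targets, and are nowhere asserted.

## Numerical choices and degenerate inputs

- Zero-phase filtering uses odd-reflection padding of roughly one settling
  length (`fs/cutoff` samples); records shorter than three settling lengths
  are rejected as too short rather than silently mangled.
- All-zero records are fixed points of the linear chain and are flagged
  `empty`; QRS detection on a flat or empty-flagged record raises a
  `no-signal` error instead of returning fabrications.
- Sample indices are 1-based inside R (native convention) and converted to
  0-based only at serialisation boundaries (JSON/WFDB export), where the
  `index_base` field says so.
- The WFDB support is a minimal single-signal format-16 reader/writer
  (gain 200 ADU/mV by default, quantisation ±2.5 µV); it exists because no
  WFDB package is available for this R runtime.
- CSV inputs not at 125 Hz are resampled (anti-alias low-pass at 0.45 × the
  target rate when downsampling, then linear interpolation onto the new
  grid) with a logged notice.

## Known limitations

- At 125 Hz, fiducial precision is limited to ±1–2 samples (8–16 ms);
  interval medians inherit a bias of similar size, inside the stated
  tolerance but visible in the numbers.
- The P detector reports absence whenever prominence is below 0.08 mV, so
  genuinely low-voltage P waves are indistinguishable from fibrillation by
  design.
- Above ~170 bpm, P and T waves merge with their neighbours; P detection
  rates drop there even on synthetic data, and measurements rely on the
  median across beats.
- The network's training loop is CPU-bound base R; it is sized for
  desk-scale experiments (thousands of short recordings at reduced width),
  not for clinical-corpus training.
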
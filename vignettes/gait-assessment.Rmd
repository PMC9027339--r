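---
title: "Methods: wearable gait assessment and Parkinsonian gait classification"
author: "pdgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable gait assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pdgait` models the analysis chain of a wearable gait "physiograph":
bilateral plantar pressure from three force-sense resistors (FSR) per
insole (toe, metatarsal arch, heel), bilateral surface EMG of the
Tibialis anterior (TA) and Gastrocnemius medialis (GM), and one wrist
accelerometer, all sampled synchronously at 100 Hz. The chain produces
(i) a qualitative biomechanical profile (arm balance, tremor grade,
strike type, lift-off), (ii) quantitative temporal parameters (cadence,
single/double support, stride-time variability), and (iii) an image
representation of the gait pattern — a 120 × 120 shifted-signal Pearson
correlation matrix per stance — classified by a compact CNN into
physiological versus Parkinsonian gait.

This vignette records the model assumptions, the tunable parameters with
their defaults and rationale, the numerical choices, and what the
synthetic generator does and does not emulate.

# Signal conditioning

**FSR conversion and polarity.** The pressure sensors sit in a resistive
divider (supply 5 V, series resistance 1 MΩ); pressure lowers the sensor
resistance and hence the measured voltage. `fsrFromVoltage()` applies
`FSR = V/(V_DD − V)·R` (domain error at or above the supply — the divider
is saturated and the resistance unidentifiable), and `fsrInvert()` flips
polarity (`max − x`) so HIGH means pressure. Resistances are carried in
kilo-ohms; no mass/pressure calibration is attempted because gait-pattern
assessment needs only the contact pattern, not podiatric units.

**Block averaging.** All channels are averaged over 8-sample rectangular
frames with 50 % overlap. We interpret the overlapping-frame construction
as *decimating*: one output value per frame, effective rate
`fs/hop = 100/4 = 25 Hz`. All downstream timing (lags in ms, stance
boundaries in s) is derived from this effective rate plus the frame-center
offset `t0 = (window − 1)/(2·fs)`, so event timestamps are true seconds on
the acquisition clock.

**Butterworth band-limiting.** 4th-order designs via `signal::butter`,
applied zero-phase (forward–backward) by default because cross-channel
event timing is the object of study; a causal switch exists. Zero-phase
application uses reflection padding with steady-state initial conditions
(the filter state that makes a step input transient-free), so constants
are passed (low-pass) or rejected (high-pass) without edge transients;
inputs must be longer than `3·(order + 1)` samples. Note that
forward–backward application squares the magnitude response; the tests
check gains against `|H(f)|²`.

**EMG.** The chain is rectification about the mean → block averaging →
0.5 Hz high-pass → 10 Hz low-pass, yielding an *activation envelope* in
the 0.5–10 Hz band. Rectification is required for the envelope semantics
of the signal space (a zero-mean carrier averages toward zero otherwise);
a `rectify = FALSE` switch band-limits the raw signal instead. The 10 Hz
ceiling reflects that muscular activity is identified, not evaluated at
motor-unit level — no MUAP-scale calibration is attempted.

**Acceleration.** Raw codes are converted to m/s² by full-scale
conversion (±2 g over signed 16-bit codes), low-passed at 30 Hz, block
averaged, then high-passed at 0.5 Hz to remove gravity. The 30 Hz
low-pass cannot follow block averaging (it would sit above the 12.5 Hz
effective Nyquist), so it is applied at the raw 100 Hz rate before
decimation; this preserves the intended 30 Hz band while keeping every
design frequency below its Nyquist. Conversion commutes with the linear
averaging, so conversion-first is a documentation choice only.

**MA and VA.** The magnitude of acceleration is the Euclidean norm of the
three dynamic axes; the variation of acceleration subtracts, per axis,
the running mean of *strictly past* samples before taking the norm.
`VA(1) := 0`: the mean over zero past samples is undefined and 0 is the
neutral, testable convention.

# Event detection

**Stance segmentation.** Per-sensor contact thresholds are
`min + 0.2·(max − min)` of each conditioned FSR series — the fraction is
a config knob (`thresholdFraction`); 0.2 of dynamic range tolerates
baseline noise while staying far below contact plateaus. A stance spans
the first to last suprathreshold sample across the foot's three sensors;
gaps shorter than `minSwingS = 0.1 s` are bridged and segments shorter
than `minStanceS = 0.2 s` discarded. Flat (zero-range) channels carry no
contact evidence and are excluded with a warning naming the channel; if
all three are flat the stance list is empty.

**Strike classification.** The onset-order rule uses a simultaneity
tolerance of 0.05 s (5 raw samples): heel leading both other sites by
more than the tolerance is a heel strike; all onsets within the tolerance
is a flat-foot strike; a leading toe is a toe-first strike. Mixed
orderings fall back to the heel-vs-toe relation. Fewer than two active
sites gives `indeterminate`. The 0.05 s default sits well below typical
heel-to-toe roll times (0.2–0.4 s).

**Lift-off versus drag.** Lift-off means *complete removal* of plantar
pressure, so it is detected against a near-zero threshold
(`liftoffFraction = 0.05` of dynamic range), deliberately lower than the
contact threshold: a light foot drag (residual toe pressure between the
two thresholds) is then caught as absent lift-off while stance
segmentation — which uses the contact threshold — still separates the
stances. A heavy drag above the contact threshold merges the segments and
instead manifests in the support fractions (reduced contralateral single
support).

**Arm balance.** Physiological arm sway reverses at stance initiation
and termination, so MA peaks (topographic prominence ≥ 0.1 of dynamic
range) should coincide with stance boundaries. Arm balance is `present`
when ≥ 60 % of boundary times have a peak within 0.15 s. When MA peaks
outnumber boundaries by more than 2.5× the coincidence rate is
uninformative — a 5 Hz tremor puts a peak within 0.15 s of *any* time
point — so dense-peak signals are graded `absent` outright.

**Tremor grading.** Tremor amplitude is estimated from the MA
periodogram as `√(2·P)` over the 4–6 Hz tremor band *pooled with its
8–12 Hz rectification image*: when arm swing is weak, the magnitude
operation full-wave-rectifies the tremor sinusoid, folding its power to
twice the frequency. The reference is the same estimate over the
0.5–4 Hz gait band. The raw band ratio overstates the underlying
tremor-to-arm-swing amplitude ratio by roughly the mixing gain of the
magnitude operation (≈ 2.4, `tremorMixingGain`, measured on quadrature
sway signals of known amplitude); after this calibration the grade
thresholds act on an amplitude-ratio scale: `< 0.15` absent,
`0.15–0.5` small, `> 0.5` large. The grading is a quantitative
operationalization of qualitative small/large tremor classes, not a
published formula.

# Temporal parameters

A "step" is any single-foot stance initiation, so one gait cycle
contributes two steps; cadence counts step events in a 10 s steady-state
window (start configurable, default the first stance initiation) and
extrapolates to one minute. Support fractions come from per-sample
boolean contact masks: single support of one side is contact of that
foot alone; double support is simultaneous contact; both in percent of
the window, and their sum never exceeds 100. The single-to-double ratio
flags a zero double-support denominator as undefined rather than
returning infinity. Stride-time variability is the sample (n − 1)
coefficient of variation of intervals between consecutive same-side
stance initiations, in percent; report formatting rounds half away from
zero to one decimal and drops a trailing ".0". Group rows are
mean ± sample sd.

# The correlation coefficient matrix

**Cross-correlation.** `xcorr()` computes
`R(m) = Σ sig1(n + m)·sig2(n)` over lags `−(N−1) … N−1`, with negative
lags by the standard symmetry `R12(−m) = R21(m)` — the convention under
which a delayed copy produces an asymmetric, displaced peak. Peak lags
convert to ms via the effective rate; symmetric ties break toward the
smallest |lag| with a configurable sign preference and an ambiguity flag.

**Shift bank.** Each of the 12 conditioned signals contributes 10
versions delayed by 0–9 steps (step = 1 effective sample = 40 ms, so the
bank spans 360 ms — covering the tens-of-ms physiological lags between
muscle activation, plantar loading and arm sway). Shifting truncates to
the common overlap; no circular wrap or zero padding, so the Pearson
statistics are not diluted by artificial samples. Delaying (rather than
advancing) is the chosen direction; the section displacement
`col_shift − row_shift` at the sectionwise argmax then has the same sign
as the cross-correlation peak lag, and the two agree within one step on
noisy delayed pairs (tested).

**Pearson guard.** A zero-variance series inside a frame makes the
coefficient undefined; affected entries are flagged `NA` (never forced to
0), excluded from rendering normalization, and drawn in a reserved
neutral gray.

**Rendering.** Coefficients map linearly from [−1, 1] to a fixed
two-anchor colormap (deep blue `(0, 0, 0.55)` → yellow `(1, 1, 0)`), and
the 120 × 120 grid is resampled to 160 × 160 px by nearest neighbor — no
axes, margins or text, so the image is a pure deterministic function of
the matrix. PNG (lossless) is the dataset format; JPEG is an optional
export and excluded from the test surface.

# The classifier

The default architecture is a from-scratch compact depthwise-separable
CNN: four blocks of 3×3 depthwise convolution (same padding) → 1×1
pointwise convolution (8, 16, 32, 32 channels) → ReLU → 2×2 max pooling,
then global average pooling and a 2-unit softmax head. Loss is binary
cross-entropy over the softmax; the optimizer default is Adam at learning
rate 0.05 with global gradient-norm clipping at 5 as a numerical
safeguard at that large step size (an SGD-with-momentum option exists).
Training is deterministic given the seed (one RNG drives initialization
and shuffling). Pretrained external backbones are deliberately not
supported: they require downloaded weights, and the compact network
trains on one CPU at desk scale.

Splitting is stratified 70/10/20 and, by default, *subject-disjoint*: all
frames of one subject stay in one partition, a stricter policy than
per-image splitting that prevents leakage between frames of the same
walk. Augmentation (off by default) is photometric only — brightness and
contrast jitter within ±10 % and translations of at most 2 px — because
matrix row/column positions encode signal identity, so flips or rotations
would change the semantics of the image. Evaluation reports the confusion
counts with the Parkinsonian class positive, the four derived ratios
(undefined ratios flagged, not NaN), and the mean test loss as the model
error.

# The synthetic gait generator

The generator produces raw 100 Hz telemetry with a ground-truth event
table, so every downstream stage is testable against known events.

**What it emulates.** Per-cycle durations jitter around the nominal
cycle with the requested stride CoV. Plantar contact is synthesized in
the *resistance* domain — a contact fraction per sensor (half-cosine
40 ms loading ramp, plateau, 80 ms release) mapped linearly onto the
rest-to-pressed resistance span (2 MΩ → 10 kΩ) and then exactly through
the divider to voltage, with 5 mV measurement noise (ADC-scale). This
makes the inverted conditioned signal linear in the contact fraction, so
threshold semantics are exact by construction. Strike types set the
onset order (heel lags 0.1/0.2 s; flat within 30 ms; toe-led reversed);
absent lift-off adds residual toe pressure at 0.12 of the dynamic range
(between the lift-off and contact thresholds; a heavy-drag level of ≥ 0.2
reproduces the merged-stance regime instead). EMG is amplitude-modulated
white noise — TA bursts at stance onset and during swing, GM from
midstance to toe-off — so the envelope chain is genuinely exercised, not
fed pre-enveloped signals. Arm sway is carried in quadrature on two axes
by a smooth phase track that advances π at every sway reversal (stance
boundary events; near-coincident boundaries share one reversal), so MA
peaks at the reversals without spectral leakage into the tremor band;
tremor is a 4–6 Hz sinusoid on the second axis, gravity a constant on the
third, and white noise on all three.

**What it does not emulate.** No musculoskeletal dynamics, no force-unit
FSR realism, no electrode artifacts, motion artifacts or sensor drift, no
freezing of gait or festination. Because right stances are phase-locked
to the midpoint of each left cycle, right stride durations average
consecutive cycle durations, and the pooled two-sided stride CoV
converges to √3/2 of the per-cycle CoV; left-side strides carry the
requested CoV exactly, and recovery tests use them. Passing tests
therefore demonstrate correctness of the *pipeline* under controlled
morphologies, not classifier performance on clinical recordings.

**Cohort defaults.** Physiological subjects: bilateral heel strike and
lift-off, arm swing 1.2–1.8 m/s², no tremor, stride CoV 3–6 %, cycle
2.0–2.8 s. Parkinsonian subjects: flat-foot / toe-led strike mixes with
one absent-lift-off case, tremor comparable to or exceeding the
(sometimes suppressed) arm swing, stride CoV 6–13 %, cycle 2.2–3.0 s.
These ranges reproduce the qualitative profile rows the detectors are
tested against (flat-foot strikes, large tremor with or without arm
balance, one drag case).

# Numerical choices and degenerate inputs

- Zero-phase filtering: reflection padding of `3·(order)` samples with
  step-steady-state initial conditions; minimum input `3·(order + 1)`.
- `VA(1) = 0`; Pearson and support-ratio degeneracies are flagged `NA`
  with an `undefined` attribute, never silently zero or infinite.
- Tie-breaks: cross-correlation peak ties resolve toward the smallest
  |lag| (sign preference configurable, ambiguity flagged); section argmax
  ties resolve toward the smallest |displacement|.
- Telemetry serialization is deterministic with ≥ 10 significant digits;
  non-finite samples are rejected before writing.
- All randomness (generator, splits, augmentation, CNN initialization
  and shuffling) is seed-driven; repeated runs with one seed are
  bit-identical.

# Problem sizes used by the test suite

The suite validates on desk-scale problems chosen to keep the chain
honest: single subjects of 8–21 cycles for event and parameter recovery
(boundaries within one 40 ms effective sample in the noiseless case;
stride CoV within ±30 % at 20 strides), a 5 + 5 cohort of 12 cycles each
(~240 stance frames) for the classification check with a 30-epoch
training run, and exhaustive brute-force oracles for the signal
primitives (cross-correlation on all random lengths ≤ 32, per-sample VA
loops, 100 random matrix entries against an independent Pearson
recomputation).

# Known limitations

- The tremor mixing-gain calibration (2.4) is derived from the
  quadrature sway model; wrist signals with very different spectral
  composition would shift the effective scale of the grade thresholds.
- Arm-balance assessment presumes MA peaks are detectable at all; very
  low-amplitude sway below the prominence floor grades as absent.
- The classifier is validated on synthetic cohorts only; no claim is
  made about accuracy on clinical recordings.
- Spatial gait parameters (stride length, velocity) are out of scope —
  the device has no distance sensing.
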
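# pdgait

Wearable gait telemetry processing and Parkinsonian gait classification.

Parkinson's disease (PD) alters gait in characteristic ways: the
physiological heel → metatarsal arch → toe plantar pressure progression is
replaced by a flat-foot (or, later, toe-led) strike, arm swing is reduced
or lost, 4–6 Hz rest tremor appears on the wrist, lift-off may give way to
foot drag, and stride-to-stride timing becomes more variable. `pdgait`
implements the full analysis chain for a wearable "physiograph" that
records, at 100 Hz, six plantar force-sense-resistor (FSR) voltages (toe,
metatarsal arch and heel of each foot), four surface EMG channels
(Tibialis anterior and Gastrocnemius medialis, both legs) and three wrist
acceleration axes. It is aimed at researchers working on sensor-based
movement analysis who need a complete, testable reference pipeline — from
raw multichannel telemetry to a clinical-style gait profile and an
image-based classifier verdict — without access to recorded patient data:
a synthetic gait generator with ground-truth event tables stands in for
the cohort.

## The method

1. **Signal conditioning.** FSR voltages are converted to sensor
   resistance through the divider relation `FSR = V/(V_DD − V) · R`,
   polarity-inverted (`max(FSR) − FSR`) so HIGH means pressure, and
   block-averaged over 8-sample rectangular windows with 50 % overlap
   (effective rate 25 Hz). EMG is rectified and band-limited to a
   0.5–10 Hz activation envelope; acceleration is converted to m/s² and
   band-limited to 0.5–30 Hz with 4th-order zero-phase Butterworth
   filters. Two arm-balance metrics are derived: the magnitude of
   acceleration `MA = √(x² + y² + z²)` and the variation of acceleration
   `VA(k) = √Σ(v(k) − mean(v[1..k−1]))²`, the deviation from the running
   mean of past readings.
2. **Gait events.** Stance phases span the first to the last
   suprathreshold plantar sample, with per-sensor thresholds at a
   fraction (default 0.2) of each sensor's dynamic range. Per-site onset
   ordering classifies the strike (heel, flat-foot, toe-first); a
   near-zero threshold distinguishes true lift-off from foot drag; MA
   peak/boundary coincidence assesses arm balance; and the 4–6 Hz MA band
   amplitude grades tremor.
3. **Gait parameters.** Cadence (steps/min), single- and double-support
   percentages, their ratio, and stride-time variability
   `CoV = 100 · σ_stride/μ_stride` over a 10 s steady-state window, plus
   cohort summaries as mean ± sample (n−1) standard deviation.
4. **Correlation features.** For each stance frame, the 12 conditioned
   signals `[MA, VA, TA_l, GM_l, FSR0_l, FSR1_l, FSR2_l, TA_r, GM_r,
   FSR0_r, FSR1_r, FSR2_r]` are expanded into 10 delayed versions each and
   all pairwise Pearson coefficients form a 120 × 120 correlation
   coefficient matrix; the argmax inside each 10 × 10 section measures the
   lag between a signal pair (cross-checked against the raw
   cross-correlation `R(m) = Σ sig1(n+m)·sig2(n)`). The matrix is rendered
   as a 160 × 160 × 3 blue-to-yellow image.
5. **Classification.** A compact depthwise-separable CNN (four 3×3
   depthwise + 1×1 pointwise blocks, global average pooling, 2-unit
   softmax) is trained on the rendered matrices — binary cross-entropy,
   learning rate 0.05, Adam, stratified subject-disjoint 70/10/20 split —
   and evaluated by accuracy, sensitivity, specificity and precision from
   the confusion counts.

## Worked example

Simulate one Parkinsonian subject (bilateral flat-foot strike, suppressed
arm swing, tremor amplitude 1 m/s², stride CoV 9 %) and assess it:

```r
library(pdgait)
sim <- simulateRecording(subjectParams("pd",
  strike = c(left = "flat", right = "flat"),
  armSwingAmp = 0.1, tremorAmp = 1.0, strideCovPct = 9,
  nCycles = 12, seed = 5), subjectId = "patient01")
space <- buildSignalSpace(sim$recording)
stances <- rbind(detectStances(space, "left"), detectStances(space, "right"))
biomechProfile(space)
#> Biomechanical gait profile
#>   arm balance: absent
#>   tremor:      large
#>   heel strike: left absent (flat-foot strike) | right absent (flat-foot strike)
#>   lift-off:    left present | right present
temporalProfile(space, stances)
#> Temporal gait parameters (window 10 s)
#>   cadence:        60 steps/min
#>   single support: left 43.2 %, right 40 %
#>   double support: 16.8 %
#>   S/D ratio:      left 2.6 , right 2.4
#>   stride CoV:     8.4 % over 10 strides
```

The profile reads like a clinical rating-scale row: arm balance is lost
(the wrist signal is dominated by tremor-induced peaks), tremor is graded
large, both feet strike flat, and lift-off is preserved. The temporal
block shows the quantitative side: the stride CoV of 8.4 % recovers the
generated 9 % jitter. One stance frame then yields the classifier input:

```r
mat <- corrMatrix(space, detectStances(space, "left")[3, ])
mat
#> CorrelationMatrix 120 x 120 (12 signals x 10 shifts, step 1)
#>   frame [128, 154) at 25 Hz, side left; 0 flagged entries
img <- renderMatrixImage(mat)   # 160 x 160 x 3, ready for the CNN
```

The full chain — cohort simulation, assessment reports, dataset
construction, training and evaluation — runs from one call
(`runPipeline(out, train = TRUE)`) or from the shell via `exec/pdgait`.

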
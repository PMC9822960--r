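# lightmyo

Gesture and grasp-force decoding for **lightmyography (LMG)** — an optical
muscle–machine interface that reads muscle contraction as changes in light
luminosity reflected through silicone and tissue — with surface **EMG** as
the electrical comparison arm. The package is aimed at biosignal/HMI
researchers who want the complete analysis chain of a five-module LMG
armband study as tested, reusable code: because no public recordings exist
for this sensor, a seeded synthetic session generator stands in for the
data and every downstream stage is exercisable end to end on one CPU.

**What's inside**

* `synthetic`: seeded sessions from a 5-module armband whose green/IR LEDs
  are time-multiplexed every 125 ms, with first-order tissue-deformation
  dynamics, drift and sensor noise; 5-channel EMG as band-limited noise
  amplitude-modulated by muscle activation; triangular grip-force ramps to
  half of maximum clench.
* `preprocessing`: sample-and-hold LED demultiplexing (5 photodiodes → 10
  logical channels), 5–500 Hz order-4 Butterworth bandpass for EMG,
  200 ms / 20 ms sliding windows with majority or strict labelling, seeded
  class balancing.
* `features`: the eight classical EMG time-domain features per window per
  channel — RMS, WL, ZC, MAV, iEMG, WAMP, VAR, LOG.
* `decoders`: random forest (150 trees), a 3-block CNN, and a Temporal
  Multi-Channel Vision Transformer (2 convs → 2×2 patch embedding → 4
  encoder layers × 4 heads), each in 5-way classification and single-output
  regression form. The deep families are implemented natively on BLAS
  matrix operations with hand-derived, finite-difference-verified
  backpropagation.
* `evaluation`: repetition-blocked 5-fold CV (classification),
  leave-one-repetition-out 10-fold CV (force regression), the NMSE fit
  score, Pearson correlation, the sensor performance index, one-way ANOVA
  modality comparison, and results-table aggregation.

The core metrics, in the field's notation:

* performance index  `I = |S̄_g − S̄_r| / (Φ_v · R_p)` — rest-to-gesture
  deflection normalized by LED luminous intensity and photodiode
  responsivity;
* fit score  `NMSE(%) = 100 · (1 − ‖x_r − x_p‖² / ‖x_r − mean(x_r)‖²)` —
  100 for identical trajectories, 0 for a mean predictor.

## Worked example

```r
library(lightmyo)

protocol <- makeGestureProtocol(rest_s = 15, gesture_s = 15, n_reps = 6)
params   <- defaultSubjectParams(seed = 42, drift_amp = 0)
session  <- simulateGestureSession(protocol, params, seed = 42)

rec <- demultiplex(session$lmg)
ws  <- slideWindows(rec, window_ms = 200, stride_ms = 20,
                    label_policy = "strict")
ws  <- balanceClasses(ws, seed = 42)
ws
#> WindowSet [LMG]: 22230 windows of 80 samples x 10 channels (200/20 ms)

spec <- modelSpec("RF", "classification", n_classes = 5, seed = 42)
crossvalClassification(ws, spec, k = 5, seed = 42)
#> CVReport: 5-fold, repetition-blocked grouping
#>   accuracy = 0.9996 +/- 0.0003
```

Read: 22230 balanced strict-labelled windows (4446 per class) from one
simulated subject; a 150-tree random forest on raw demultiplexed windows
classifies held-out repetitions at 99.96% ± 0.03% — on synthetic data the
classes are separable by channel mean levels, so all families sit near
ceiling (`gestureBenchmark()` runs all three). The force arm:

```r
force <- forceBenchmark("TMC-ViT", seed = 42)   # 10 ramps, one per fold
cvMeans(force)                                   # pearson ~0.99, NMSE >= 85
```

A thin CLI over the same functions is installed at
`system.file("cli", "lightmyo.R", package = "lightmyo")` with subcommands
`simulate`, `preprocess`, `features`, `train`, `evaluate`, `report` and
`bench-sensor`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lightmyo.R",package="lightmyo"))')" \
  simulate --experiment gesture --subjects 2 --seed 7 --out sessions/
```

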
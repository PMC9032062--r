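---
title: "Detecting rotational activity in multi-electrode atrial electrograms"
author: "rotoregm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rotational activity in multi-electrode atrial electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotoregm)
```

## The problem

During atrial fibrillation, self-sustaining re-entrant wavefronts ("rotors")
may act as drivers that maintain the arrhythmia. A star-shaped mapping
catheter with 5 splines and 20 electrodes records unipolar electrograms in
direct contact with the atrial wall; when its channels are arranged by
concentric rings, a rotor appears as a *staircase* of local activation
times (LATs) that climbs (or descends, depending on the rotation's
chirality) across the ring and spans the full activation cycle,
rotation after rotation.

`rotoregm` implements this detection problem end to end:

* a **catheter model** (`build_layout()`, `ring_order()`,
  `bipolar_pairs()`, `spline_rotation()`) fixing the geometry and channel
  orderings every other component consumes;
* a **synthetic electrogram simulator** (`simulate_cohort()`,
  `lazy_cohort()`) that generates multi-patient cohorts of 30 s, 1 kHz,
  20-channel acquisitions with ground-truth rotor annotations;
* the **signal-conditioning pipeline** (`eg_bandpass()`, `eg_notch50()`,
  `derive_bipolar()`, `eg_resample()`, `percentile_normalize()`,
  `lat_train()`);
* a **rule-based staircase detector** (`detect_rotational_activity()`)
  that serves as labeling oracle and standalone detector;
* a **dataset builder** (`build_dataset()`) producing balanced, augmented,
  patient-split window sets;
* three **neural classifiers** (`crnn_spec()`, `simple_spec()`,
  `aticnn_spec()`) with a built-in Adam/backpropagation engine; and
* **evaluation utilities** (`classification_metrics()`, `roc_auc()`,
  `run_grid()`).

## The catheter model

Electrodes are indexed `(spline, position)`, 0-based, with splines ordered
counterclockwise by angle (72° apart by default) and positions ordered
inner to outer at radii 2, 5, 8, 11 mm. Only the relative order of radii
matters to ring logic; absolute values matter only to the simulator's
travel-time computations. A *ring* is the set of same-position electrodes
across all splines; chirality is defined relative to the counterclockwise
ring order: activation time increasing with spline angle is labeled
`"ccw"`. Bipolar channels are adjacent within-spline pairs, 15 for the
default layout.

## The synthetic cohort

No public recording of this catheter's signals exists, so the simulator is
the package's test bed. It is a *statistical* emulator of activation
patterns, not a biophysical tissue model.

Each acquisition is built from an activation schedule:

* **planar** and **focal** backgrounds: periodic wavefronts whose
  per-electrode delays follow the geometry (projection onto a direction, or
  distance from a source, divided by a 0.5 mm/ms conduction velocity), so a
  ring's activation spread stays below ~44 ms — far under half a cycle;
* **rotor episodes**: the electrode at ring angle θ activates at
  `t0 + k·CL + (θ/360)·CL`, a staircase spanning 80 % of the cycle on a
  5-electrode ring; all four rings share one core (the simplest
  single-core choice), so electrodes on a spline activate together;
* **fractionation**: on marked electrodes each activation renders as a
  burst of 3–5 low-amplitude deflections within 40 ms — the classic
  false-positive surrogate of rotational activity, included so detector
  and classifier specificity are non-trivially exercised.

Cycle lengths are drawn per episode (and per background) from a truncated
normal with mean 166.8 ms and SD 36.1 ms, floored at 100 ms — the
clinical distribution of rotor cycle durations in persistent AF. The
refractory floor of an electrode's activation train is 90 ms: it must sit
*below* the 100 ms cycle floor, otherwise cycles in \[100, 120) ms would
have alternate activations pruned and a clean staircase could neither be
scheduled nor detected; physiologically, atrial refractoriness during
fibrillation shortens below the shortest sustained cycle. Rendered
deflections are derived from the refractory-pruned activation train at
finalization, so a waveform can never contain activations that violate the
schedule's invariant.

Each activation renders as the negated first derivative of a Gaussian
(`w(t) = −A (t/σ) exp(1/2 − t²/2σ²)`, σ = 2 ms, A ≈ 1 mV with ±20 %
jitter): a biphasic deflection whose **steepest negative slope falls
exactly at the scheduled LAT**, which is what makes the maximum-negative-
slope LAT convention exact by construction. White noise (default
0.05 mV), a periodic common-mode far-field bump (0.2 mV, 700–900 ms
period, cancelled exactly by bipolar derivation) and 50 Hz interference
(0.05 mV) complete the model. Clinical amplitude statistics for these
signals are not published; the amplitudes here are configurable
placeholders chosen to give a realistic signal-to-noise ratio. All
randomness flows from one seed; `lazy_cohort()` regenerates acquisitions
on demand from per-acquisition seeds so large cohorts never need to be
held in memory.

What the simulator does **not** emulate: wavefront curvature and meander,
electrode contact loss, catheter motion, spatially correlated noise, and
amplitude heterogeneity across the atrium. Tests passing on synthetic data
therefore demonstrate the pipeline's correctness and the architecture's
capacity, not clinical performance.

## Signal conditioning

Band-pass filters follow the clinical acquisition settings: 30–240 Hz for
bipolar, 0.1–100 Hz for unipolar channels, plus a 50 Hz notch at the
native 1 kHz rate. The filter family and order are not part of the
acquisition standard, so the package uses 4th-order Butterworth designs
applied forward–backward: zero phase distortion is essential because the
rule detector's LAT timing must survive filtering. Down-sampling applies a
zero-phase anti-alias low-pass before index decimation, keeping
`floor(n·target/fs)` samples (the anti-alias pass is skipped when a
recorded pass band already ends below the target Nyquist). Binary
activation trains are re-binned by index arithmetic instead of filtered,
preserving their 0/1 nature.

Windows are normalized per window, over all channels jointly, by mapping
the 2nd and 98th percentile of the pooled values to 0 and 1 and clipping —
this both standardizes scale and suppresses isolated artifacts. A
degenerate window (equal percentiles) maps to the constant 0.5, keeping
outputs inside \[0, 1\] and symmetric. Per-window scope matches the unit of
computation seen by the classifiers at train time.

## The staircase rule detector

The rule detector mirrors the published description of the clinical
rotational-activity module:

1. **LATs** are the instants of maximum negative slope. Per channel, local
   minima of the first derivative below a threshold are accepted greedily
   by steepness under a 90 ms refractory spacing. The default threshold is
   20 % of the channel's 98th-percentile absolute derivative, floored at 4
   robust (MAD) standard deviations of the derivative so broadband noise
   cannot seed spurious detections. Detection runs on band-limited signals
   (the unipolar clinical band plus notch) unless the input is already
   filtered.
2. The **dominant cycle** is the pooled median of consecutive inter-LAT
   intervals — robust to missed detections, which only contribute doubled
   intervals.
3. The **ring staircase scan** anchors a frame at every LAT of every ring
   electrode, closing at that electrode's next activation (the local
   cycle). A frame is a candidate rotation if every ring electrode has
   exactly one LAT inside, the LATs are strictly monotone under some
   cyclic rotation of the starting electrode (direction gives chirality),
   the span exceeds half the local cycle, and the staircase is *uniform*
   (each step within 0.25–1.8 of the mean step). Anchoring at all
   electrodes probes every phase of the rotation, so an episode boundary
   cannot clip a rotation that some phase sees whole; the local (frame)
   cycle, rather than the acquisition-global estimate, makes the span
   criterion correct when a fast rotor sits inside slow background. The
   uniformity condition implements the "staircase" shape itself: a true
   rotor advances by one fifth of the cycle per electrode, whereas
   chance-monotone jitter patterns on fractionated channels have grossly
   uneven steps.
4. **Grouping**: same-chirality candidates chained with gaps of at most
   one cycle form an event; because every anchor phase contributes a
   candidate per rotation, the rotation count is estimated from the
   chain's time span over the local cycle (an n-rotation chain spans
   (n − 0.2) cycles). Events of fewer than 3 rotations — "more than 2
   consecutive" read literally as ≥ 3 — are discarded. Overlapping
   same-chirality events across rings merge, keeping the maximal rotation
   count.

On clean simulated cohorts this recovers essentially every episode with
exact chirality and sub-millisecond LAT error, and flags no rotor-free
acquisition (the test suite asserts ≥ 0.95 for both sensitivity and
per-acquisition specificity over ≥ 100 acquisitions).

## Dataset construction

Acquisitions are conditioned for one of three input representations
(bipolar, unipolar, or binary unipolar-LAT trains), cut into sliding
windows (500 or 2500 ms, 50 % overlap, trailing remainder dropped), and
labeled against rotational events. The labeling rule — a window is
positive when an event overlaps it by at least one full rotation — is a
package choice: the mapping from 30 s acquisition annotations to window
labels admits several readings, and one full rotation is the smallest
overlap in which the window actually contains a rotation; an "any-overlap"
alternative is available. Classes are rebalanced 1:1 per patient (keeping
all positives and a seeded negative subsample; patients with no rotational
activity are dropped entirely), patients are split 90:10 chronologically
into train and test, and validation is a stratified window-level carve-out
of the training patients (a patient-level validation split would also be
defensible; the window-level rule matches the reported train/validation
window counts' granularity). Ring-permutation augmentation (the 5 spline
rotations; optionally the 4 flip combinations, for 20 variants) applies to
the training partition only.

## The classifiers and the training engine

Three architectures are provided as specification records:

* **`simple_spec()`** — flatten, then dense 128 → 64 → 1 (rectifier
  activations, sigmoid output). A deliberate floor: it sees no temporal
  structure.
* **`aticnn_spec()`** — 13 time-axis convolutions of kernel 3 in five
  blocks (2, 2, 3, 3, 3 layers; 64–256 channels) with pooling after each
  block, electrodes entering as input channels, then two long
  short-term-memory layers of 32 units. The published description of this
  comparator names only the convolutional block and the two memory cells,
  so no attention stage is implemented.
* **`crnn_spec()`** — the package's main model: 37-sample symmetric time
  padding, input batch normalization and dropout, three blocks of
  (rectangular-kernel convolution, batch normalization, leaky rectifier
  (slope 0.3), boundary-truncating max pooling, 30 % dropout), two gated
  recurrent layers of 32 units, one sigmoid unit. Convolutions use
  size-preserving padding — required to reproduce the published
  activation-shape chain (1324 × 20 → 662 × 19 → 220 × 6 → 55 × 1 for a
  1250 × 20 input) — and pooling truncates at boundaries. The 23 × 5
  kernel's long side runs along the time axis by default: rectangular
  kernels exist to capture longer temporal dependencies, and that reading
  places the long side on time; the transposed orientation is one flag
  away, and the shape chain is identical either way.

No deep-learning framework is assumed: the package carries its own
reverse-mode engine (single-precision im2col/GEMM convolution kernels in
compiled code, double-precision recurrent and dense layers in R) with Adam
optimization, binary cross-entropy on logits, minibatches of 32, a
learning-rate grid of {1e-2, 1e-3, 1e-4} selected on validation accuracy,
and early stopping with best-weight restoration. Backpropagation is
verified against central finite differences in the test suite. Batch
normalization uses ε = 1e-3 and running-statistics momentum 0.9 — the
shorter memory makes inference statistics usable within small epoch
budgets. Initialization is Glorot-uniform from the model seed; training
randomness (shuffling, dropout) flows from the training seed, so fits are
exactly reproducible.

## Evaluation

`classification_metrics()` computes accuracy, precision, recall,
specificity and the Matthews correlation coefficient from the confusion
matrix, with the zero-denominator convention MCC = 0 (a classifier that
ignores its input carries no correlation; this also reproduces the
published 0.000 entries for degenerate all-positive rows). Undefined
ratios are reported as 0 with a degeneracy flag. `roc_auc()` sweeps
thresholds over the unique scores and integrates by the trapezoid rule;
the result equals the Mann–Whitney rank statistic (ties one half), which
the tests verify by exhaustive pair counting and against an independent
ROC implementation. The decision threshold for confusion-based metrics is
0.5. `run_grid()` trains and evaluates every (model, input type, window
length, sampling rate) combination with per-cell seeds, marking failed
cells and continuing.

## Study sizes and numerical choices

The test suite runs two synthetic studies chosen to exercise the
full pipeline at desk scale:

* *Rule-detector recovery*: 100 noiseless acquisitions (20 patients × 5),
  default simulator settings otherwise.
* *Learnability*: a 48-patient × 11-acquisition cohort at default noise,
  bipolar windows of 2500 ms at 500 Hz, capped at 2,000 balanced training
  windows; the convolutional-recurrent model trains for one epoch at
  learning rate 1e-3 (validation checked every 14 steps, best weights
  restored), the dense baseline trains with the full learning-rate grid
  and three epochs. One epoch is enough here because the synthetic classes
  are cleanly separable; the baseline is given the larger budget so its
  lower score cannot be attributed to under-training.

Other numerical choices: degenerate normalization maps to 0.5; pooling
argmax ties resolve to the first (lowest-index) element; event matching in
agreement computations requires 50 % overlap of the shorter interval;
window start positions are sample-aligned by flooring.

## Known limitations

The simulator's single-core, geometry-driven activation model makes the
synthetic task easier than clinical data; scores on it are upper bounds.
The rule detector's thresholds (slope fraction, refractory, uniformity
band) are package choices exposed as parameters, not published constants.
The training engine is CPU-bound and single-threaded beyond BLAS; it is
sized for the bundled studies, not for large-scale hyperparameter sweeps.
Models are tied to the star-catheter topology; other electrode layouts
require retraining and a new `catheter_layout`.
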
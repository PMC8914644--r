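---
title: "Counting insects in camera-trap images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting insects in camera-trap images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electronic insect traps ("e-traps") photograph their internal sticky floor
and report to a monitoring server. The quantity of interest is not *which*
species was captured but *how many* arthropods are present: a change in the
count is what should trigger an upload and an alert. `trapcount` implements
this counting pipeline end to end at desk scale: labeled-image synthesis,
a small counting-by-regression CNN, 8-bit post-training quantization for
microcontroller deployment, the counting-accuracy statistic, and a
duty-cycle simulator with an energy model.

Counting is framed as **regression**: the network maps an image directly to
a scalar count, skipping detection, localization, and species recognition.
This keeps the model small enough for a microcontroller and is more robust
to partial insect overlap than box-based detectors.

## Synthetic scenes with exact ground truth

Hand-labeling thousands of trap photos is impractical, so labeled data are
*composed*: insect cutouts ("sprites", luminance raster + transparency
mask) are pasted onto trap-floor backgrounds at random rotations and
positions. Because the generator controls the number of pasted insects, the
ground-truth count `Mc` of every image is exact and is encoded in its
filename (`{split}_{id}_count{Mc}.png`).

The reference design that the defaults reproduce:

* a bank of 100 insect cutouts, split 70/30 into train/test sprites so no
  insect seen at training time appears in a test scene;
* per scene, a count drawn from 0–6, each sprite rotated uniformly in
  [0, 360) degrees and placed by rejection sampling with **zero mask
  overlap**;
* a balanced database: 2,000 train-pool scenes per class (14,000 total,
  split 9,800/4,200 into train/validation at the image level) and 200 test
  scenes per class (1,400), at 240 x 240 grayscale.

Design choices the source design left open, fixed here:

* **Overlap.** "Without significant overlap" is tightened to *zero* binary
  mask overlap, and the occupancy grid additionally stores a 1-px dilation
  halo, so placed insects never touch. This makes the label verifiable: with
  illumination jitter off, the number of connected components of
  `|image - background|` equals `Mc` exactly, and the test suite checks this
  on hundreds of scenes.
* **Backgrounds.** The original trap had a folder of background photos that
  "differ slightly". The stand-in is a family of procedurally generated
  trap-floor textures (base gray 0.82 with two scales of smooth noise),
  eight variants by default, plus per-scene brightness jitter of +/-5% and
  faint smooth noise. Real background photos can be substituted.
* **Sprites.** When no photographed cutouts are supplied, a procedural
  synthesizer provides them: an elliptical body (length 12–60 px at the
  240 px scale, aspect 2–5), a head disc, 0–8 thin polyline appendages,
  optional paler wing lobes, body luminance 0.05–0.35. Every mask is a
  single connected component, and sprites are bit-reproducible from their
  seed. Wing luminance is capped at 0.6 so no part of an insect can fade
  into the (brighter) background. Rotation uses bilinear resampling with
  canvas expansion and re-binarizes the mask at 0.5; thin limbs can shear
  into fragments under resampling, so only the largest connected component
  is kept — a rotated sprite is always one insect.
* **Rounding of the sprite split.** `round(n * fraction)` with ties toward
  the training side (70 of 100 at fraction 0.7).

What the procedural scenes do **not** emulate: debris, insect decay,
shadows, focus blur, specular highlights, or insects clipped at the trap
edge. Passing tests on this data show that the pipeline's machinery is
correct and that the model class can count well-separated dark shapes of
unseen morphology; they do not certify field accuracy on real trap photos,
which depends on photographed cutouts and real backgrounds.

## The counting regressor

The network is deliberately tiny — the deployment target is a
microcontroller whose memory bounds the serialized graph at 0.55 MB. The
default architecture (used everywhere in the package) is:

| stage | operation |
|---|---|
| 4 blocks | 3x3 conv (same size, replicate padding) -> ReLU -> 2x2 max pool, channels 16-32-64-64 |
| head | global average pooling -> 1 linear unit |

about 60k parameters in total. Convolutions pad by edge replication rather
than zeros: a zero pad would surround every scene with a dark frame that
resembles insect pixels and, at small input sizes, contaminate most cells
of the final pooling grid. The stack is fully convolutional, so the
same weights serve the 64 px desk-scale experiments and the 240 px
deployment resolution. The output head is linear and unbounded; converting
the scalar to a count (round half away from zero, clip at 0) happens in the
evaluator, keeping MSE gradients unconstrained.

Training follows the deployed recipe: MSE loss, Adam with learning rate
0.001 (beta1 0.9, beta2 0.999), batch size 32, up to 240 epochs, with
augmentation applied to training images: horizontal and vertical flips with
probability 0.5 each, rotation with probability 0.5, zoom with probability
0.2. The recipe states the probabilities but not the magnitudes; the
package defaults are rotation +/-20 degrees and zoom in [0.8, 1.2]. Rotation augmentation expands the canvas
and resizes back (a rotation composed with a slight zoom-out) so that no
insect ever leaves the frame — a same-canvas rotation would corrupt corner
labels.

Early stopping is regulated by the validation set, monitoring the mean
counting accuracy (alpha, below) of rounded predictions with patience 20;
the best-validation weights are restored. Whether the original recipe
monitored alpha or exact-match accuracy is not stated; alpha was chosen
because it is the reported statistic.

All randomness — weight init, shuffling, augmentation draws — flows from
one run seed through a deterministic seed-derivation chain, so training is
reproducible bit-for-bit given (config, manifest, seed). The conv/pool
kernels are im2col + GEMM routines in C++ (RcppArmadillo); backprop is
verified against numerical differentiation in the test suite.

## Counting accuracy

Per image, with true count `Mc` and rounded prediction `Ac`:

    alpha = 1 - |Mc - Ac| / Mc

Two edge cases are resolved explicitly:

* **`Mc = 0`.** The definition divides by zero for empty scenes, yet a
  background-class accuracy is part of per-class reporting. The package
  substitutes the denominator `max(Mc, 1)`, which reduces to exact-match
  scoring for the empty class and is continuous with the definition at
  `Mc = 1`. Every report carries this convention string.
* **Negative alpha.** The statistic is *not* floored at zero
  (`Mc = 1, Ac = 3` scores -1); the exact-match rate is reported alongside
  for interpretability.

The reported mean is the unweighted per-image mean; on a balanced test set
this coincides with the mean of class means. The test suite recomputes the
mean by brute-force enumeration over all per-image pairs on every run.

## Quantization

Post-training quantization converts conv and dense weights to int8
(symmetric, per output channel) and calibrates each ReLU output's range on
a representative set of 128 training images (seed-pinned); during quantized
inference activations are quantized affinely to uint8 per layer, while
input/output tensors and biases stay float32. The serialized artifact is a
flat binary — a short JSON header (architecture, scales) followed by raw
int8 weight bytes — roughly one quarter the float32 graph's size. Hardware
compiler passes (e.g. TPU-specific repacking) are out of scope; the
reference deployment's 0.55 MB artifact size is used as the binding budget, which the
default architecture meets with a wide margin at any input resolution.

## Duty cycle and energy model

The deployed trap wakes once per day at night and runs: load model ->
capture with flash -> infer count -> upload iff the count differs from the
previous day (the first observation always uploads — the source design is
silent on initialization) -> store the picture -> deep sleep. The upload
transport is an injected interface; the default mock records payloads, as
the WiFi/HTTP stack is firmware out of scope. Over any schedule, uploads =
1 + number of day-to-day count changes; this is property-tested against an
oracle counter.

Battery life uses per-phase consumption figures shipped as YAML fixtures
for the four measured device configurations. With `cycles_per_day` wake
cycles displacing sleep time:

    daily_mAh = [sleep_mA * (86400 - cycles * active_s)
                 + cycles * sum(current_mA * duration_s)] / 3600
    days      = capacity_mAh / daily_mAh

For the ESP32 profile (sleep 6 mA; 180 mA x 2 s capture, 85 mA x 51 s
inference, 150 mA x 3.5 s store+upload, 70 mA x 6.5 s other; 6,700 mAh)
this gives **46.1 days**. The reference figures for this row are internally
inconsistent: the row's cells sum to 5,675 mA.s but 5,595 mA.s was printed,
and the quoted 50-day lifetime does not follow from the row under any
reading of it. The estimator implements the formula; the discrepancy is
documented rather than reconciled, and the tests accept the 45–51 day band.

## Desk-scale problem sizes

The validation experiments in the test suite and the acceptance script run
a scaled-down replication chosen to keep a full train-evaluate cycle to a
few CPU-minutes: 64 x 64 scenes, 300 scenes/class train pool (split 70/30),
50 scenes/class test, training capped at 30 epochs. At this scale the
trained regressor reaches a mean test alpha above 0.95 on sprites it has
never seen — the same headline level as the full-scale system — and the
int8/float accuracy gap stays within 0.02. The full-scale per-class values
depend on the original photographed insect cutouts and are not
reproduction targets for procedural sprites.

## Known limitations

* Scenes are strictly non-overlapping; the model's robustness to overlap is
  not exercised.
* Procedural sprites are darker than the background by construction; field
  images with low-contrast insects will be harder.
* The quantized inference path simulates int8 arithmetic with float
  operations (identical rounding decisions, not identical bit patterns to
  any particular embedded runtime).
* `alpha` weights errors relative to the true count, so one miscount on an
  empty or single-insect scene costs as much as six on a six-insect scene;
  the exact-match rate is the more conservative companion statistic.
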
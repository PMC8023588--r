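---
title: "Annotation-efficient frame selection for IVOCT segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-efficient frame selection for IVOCT segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intravascular optical coherence tomography (IVOCT) acquires hundreds of
cross-sectional frames per pullback, and pixel-wise annotation of coronary
calcification is slow, expert work. When a 2-D segmentation network is
applied slice by slice, neighbouring frames are so strongly correlated along
the pullback axis that annotating all of them wastes effort. `octsubset`
implements and evaluates two ways of choosing a fraction of frames per
expert-identified volume of interest (VOI) for annotation:

* **equal z-spacing** — every *k*-th frame of the ordered stack
  (`equal_spacing_indices()`), exploiting spatial correlation directly;
* **deep-feature clustering** — train a small convolutional autoencoder on
  the VOI's frames, represent each frame by its bottleneck features, reduce
  them with PCA, run k-medoids with the cluster count equal to the number of
  frames to be selected, and annotate the medoid frames
  (`clustering_sample()`).

The package also contains everything needed to measure the consequences of
that choice: polar-domain preprocessing, a compact trainable U-net pixel
classifier, pixel-level evaluation, the multi-model comparison protocol, and
a synthetic phantom generator that stands in for clinical data in every test.

## Preprocessing (polar domain)

Raw frames live in the polar `(r, theta)` representation: one column per
A-line, one row per depth sample. `preprocess_voi()` applies, per frame:

1. **Guidewire zeroing.** The metal guidewire occludes a contiguous
   (circularly wrapping) run of A-lines. `detect_guidewire_alines()` flags
   the longest circular run whose beyond-lumen intensity sum falls below
   `median - 3 * MAD` of all A-line sums (minimum width 3); phantom ground
   truth can bypass the detector. Flagged A-lines are set to exactly zero,
   in image and mask.
2. **Pixel-shift alignment.** Each A-line is translated radially by its
   lumen offset so that row 1 is the lumen boundary everywhere. Shifts are
   integer, so masks stay binary; vacated deep pixels are zero-filled; the
   shifts are recorded and invertible within the retained depth.
3. **Crop.** Only the first 200 radial pixels below the lumen (about 1 mm
   at a 5 micrometre pitch) are kept — deeper signal is attenuated noise.
4. **Log transform and smoothing.** `log(x + 1e-6)`, per-frame min–max
   rescaling to [0, 1] (networks need bounded input; the offset keeps
   zeroed pixels finite and they map back to 0), then 7×7, sigma 1 Gaussian
   filtering with replicate padding. The mask is cropped identically but
   never filtered, and guidewire columns are re-zeroed after filtering so
   the all-zero guarantee survives the blur.

## The selectors

`target_count(n, ratio)` is `ceiling(n * ratio)`, never below one frame.
Equal spacing starts at frame 0 with stride `round(1 / ratio)`; for the
standard ratios (1/2, 1/3, 1/10) this yields exactly `target_count` frames.
For other ratios the stride set is trimmed from the end or padded with
evenly spread unselected frames so the cardinality contract holds for every
ratio.

The clustering selector composes four stages, all per VOI:

* `train_autoencoder()` — a strided-convolution encoder (3×3 kernels,
  stride 2, widths 4/8/16/32 by default) with a mirrored nearest-neighbour
  upsampling decoder and **no skip connections**: with skips the network
  could route information around the bottleneck and the features would be
  uninformative. Mean-squared-error reconstruction loss, Adam, 100 epochs at
  learning rate 0.001 and batch size 64. The 1-channel output projection
  sits at half resolution, followed by the final mirrored upsample: on
  Gaussian-smoothed inputs the half-resolution representation is nearly
  lossless, and the two most expensive layers halve in cost.
* `extract_bottleneck_features()` — global average pooling of each
  bottleneck channel (32-dimensional by default). Pooling makes the
  dimension independent of frame size and keeps the PCA well-conditioned
  with few frames; full flattening is available (`feature_pool =
  "flatten"`) when spatial position should be preserved.
* `reduce_pca()` — centre, then keep the smallest number of leading
  components whose cumulative explained variance reaches 95% (capped at
  `n - 1`). Identical frames (zero variance) degrade to a single constant
  component with a warning. No whitening is applied.
* `k_medoids()` — PAM on Euclidean distances: greedy build (first medoid
  minimises total distance, each next one maximises cost reduction), then
  repeated best-improving swaps until none exists. Every tie breaks toward
  the lowest frame index, so the algorithm is fully deterministic and needs
  no randomness; the `seed` in the interface is recorded for provenance
  only. On instances small enough to enumerate, PAM attains the exhaustive
  optimum in well over 95% of random cases and can never beat it.

Medoid frames are returned in ascending order. When the requested count
reaches the VOI size, all frames are returned and no autoencoder is trained.

## Segmentation stage

`build_segmenter()` is a compact U-net: per stage a stride-1 convolution
(the skip source) and a stride-2 down-convolution; a middle convolution;
decoder stages of nearest-upsample + convolution + skip concatenation +
convolution; and a 1-channel sigmoid head at input resolution. It is
randomly initialised (He scaling) — a deliberately small, from-scratch
substitute for a large pretrained encoder, sized for CPU training.

Training (`train_segmenter()`) uses Adam and weighted binary cross-entropy
with dataset-level class weights inversely proportional to prevalence and
summing to one (`class_weights_from_prevalence()`; at 10% calcific pixels
the weights are 0.9/0.1). Early stopping halts when the validation loss has
not improved for 5 consecutive epochs, and the best-epoch weights are
returned. Probability maps are thresholded at 0.5 for F1; average precision
is threshold-free.

Two robustness details, both deterministic given the seed:

* **Restart on plateau.** With a small net and few frames, roughly a
  fifth of runs stall in a poor basin, recognisable by a final training
  loss an order of magnitude above the converged level. If after at least
  10 epochs the final training loss exceeds a quarter of the first epoch's,
  training restarts from a re-derived seed, at most `max_restarts` (2)
  times.
* **Single-precision engine.** Both training loops run in single-precision
  C++ (im2col + GEMM convolutions); the double-precision R implementation
  of the identical computation is retained internally and the test suite
  asserts per-epoch loss agreement between the two paths.

## Evaluation

`f1_per_class()` pools pixels over all frames of the evaluation set
(per-frame AP is available where frames are the unit of analysis).
`average_precision()` ranks pixels by predicted probability and accumulates
the stepwise precision–recall area; frames without a single calcific pixel
make the curve undefined and are excluded, which is exactly the treatment
of frames from normal VOIs. `calc_attributes()` reduces an aligned mask to
clinical lesion descriptors — circumferential angle, minimal depth from the
lumen, and mean radial thickness over the involved A-lines (the mean is our
choice of reduction; it is recorded in the output) — and `bland_altman()`
summarises prediction/ground-truth agreement as bias and 95% limits.
`compare_models()` runs the paired t-test across frames, with an exact
sign-flip permutation fallback when the paired differences are constant
(zero variance makes the t-test degenerate), and the one-sample Wilcoxon
test against a baseline AP.

## Experiment protocol

`make_split_plans()` rotates every VOI through a stratified held-out set
exactly once across 4 iterations and deals each iteration's training VOIs
into 5 stratified folds; VOIs, never frames, are the unit of splitting, so
no frame of an evaluation volume is ever trained on. `run_model()` applies
a sampler to each training VOI (with a per-VOI seed derived from the
sampler seed, so plans are independent of processing order), optionally
grid-searches learning rate and batch size by the inner cross-validation
(three-way train/validation/test rotation; the best point maximises mean
calcific F1 over test folds), then retrains on the full sampled training
set for the rounded mean number of epochs the CV runs took, and evaluates
every frame of the held-out VOIs. During CV, training and validation folds
use the sampled frames — a scarce-annotation protocol only has labels for
selected frames — while test folds and the held-out set are evaluated on
all frames. `run_seven_model_comparison()` runs the all-frames baseline
plus both samplers at ratios 1/2, 1/3 and 1/10 on identical split plans
and segmentation seeds, so the sampler is the only varying factor.
`run_fewer_vois_experiment()` fills the same one-tenth frame budget with
whole VOIs in shuffled order (the VOI crossing the budget is included
whole; a prefix with no calcification VOI is extended until it has one,
since the weighted loss is undefined without positives) and compares ten
such models per iteration to the one-tenth-clustered baseline with the
one-sample Wilcoxon test.

## The phantom generator

`generate_voi()` emulates the statistical structure of clinical polar
IVOCT: an eccentric, slowly precessing lumen; a guidewire shadow a few
degrees wide drifting along the pullback; tissue as an exponentially
attenuating profile under multiplicative exponential speckle (image
formation is a modelling choice — it makes the log transform and Gaussian
smoothing meaningful, not a claim about OCT physics); and, in calcification
volumes, a signal-poor lesion with a sharp front-border intensity step
whose arc, depth and thickness drift smoothly in z, so neighbouring frames
are correlated. Masks mark the lesion, are zero inside the lumen and in
guidewire A-lines. Defaults: 496 A-lines × 400 radial pixels (so the
200-pixel crop keeps about half the depth), lesion arc 130 degrees and
thickness 110 pixels — calibrated once, by bisection, so that a mixed
dataset at the study-like 26:34 normal:calcification VOI ratio lands near
10% calcific pixels over the preprocessed frames, the prevalence regime the
class weighting is designed for. `generate_dataset()` draws VOI lengths
log-uniformly from [10, 200] frames, matching both the clinical range and
its mean (about 62 frames per VOI).

Two structured modes exist for testing the selectors: `archetypes` plants k
distinct lesion morphologies in contiguous blocks within one VOI (used to
verify that clustering recovers planted structure that equal spacing
misses), and `lesion_params$random_morphology` randomises each VOI's lesion
arc, extent, depth and thickness (used to build datasets heterogeneous
across volumes for the fewer-VOIs experiment).

What the phantom does **not** emulate: OCT optics (attenuation
coefficients, catheter artefacts other than the guidewire shadow), layered
vessel-wall anatomy, other plaque types, or annotation noise. Passing tests
on phantoms therefore demonstrate that the pipeline's machinery behaves as
specified and that the selection effects exist when inter-frame redundancy
and lesion heterogeneity do — they do not certify clinical performance
numbers.

## Problem sizes used in the shipped tests

The test suite replicates the protocol's effect directions at desk scale,
chosen so the full suite trains dozens of networks in tens of minutes on
one CPU core:

* autoencoder reconstruction contract: one 100-frame calcification VOI at
  full frame size (496×400, cropped to 200), the prescribed 100-epoch
  schedule; reconstruction error lands well under the 0.03 bound;
* archetype recovery: 40-frame VOIs (96 A-lines × 120 radial pixels) with
  three planted morphologies in 22/12/6-frame blocks, one-tenth sampling,
  ten seeds;
* sampler comparison: five master seeds, each with 4 normal + 10
  calcification archetype-structured VOIs of 24–40 frames at 64×96;
  one-tenth clustering vs equal spacing, compact U-net (widths 4/8/16),
  100 fixed epochs;
* fewer-VOIs experiment: 10 normal + 20 calcification VOIs of 8–14 frames
  with per-VOI random morphology; 4 iterations × 10 shuffles against the
  clustered baseline.

Every size scales up by configuration (`phantom_config()`,
`experiment_config()`); nothing in the implementation depends on the
desk-scale values.

## Known limitations

* The autoencoder and U-net are deliberately small; absolute F1/AP values
  on phantoms are not comparable to clinical-scale results — only
  directions and contracts are.
* PAM is exact-ish but O(k·n²) per sweep; for VOIs far beyond a few hundred
  frames a faster k-medoids would be warranted.
* The guidewire detector assumes a single shadow; bifurcation shadows or
  multiple wires would need the annotation path.
* Attribute extraction assumes the aligned representation (lumen at row
  zero); angles are counted over involved A-lines, which for multiple
  disjoint lesions yields the union arc, not per-lesion arcs.
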
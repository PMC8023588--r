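# octsubset

Annotation-efficient training-image selection for intravascular OCT
(IVOCT) segmentation.

## The problem

Segmenting coronary calcification in IVOCT pullbacks with a slice-wise 2-D
network requires pixel-level annotations, and a single pullback holds
hundreds of highly correlated frames. Within an expert-identified volume of
interest (VOI), which fraction of frames actually needs annotation, and
which frames should they be? `octsubset` implements two selectors and the
full protocol for comparing them:

* **Equal z-spacing** — every *k*-th frame of the ordered stack (for a
  sampling ratio of one-third, every third frame).
* **Deep-feature clustering** — train a compact convolutional autoencoder
  on the VOI (100 epochs, learning rate 0.001, batch size 64), collect
  bottleneck feature vectors per frame, reduce them by PCA to the smallest
  subspace explaining at least 95% of the variance, then run k-medoids
  (PAM) with k equal to the number of frames to annotate; the medoid
  frames are selected.

Around the selectors the package provides: polar-domain preprocessing
(guidewire-shadow zeroing, lumen pixel-shift alignment, 200-pixel radial
crop, log transform, 7×7 σ=1 Gaussian smoothing); a compact U-net pixel
classifier trained with prevalence-weighted binary cross-entropy
(weights `w_calcific = 1 - p`, `w_other = p`, summing to one) and
patience-5 early stopping; pixel-level evaluation (per-class
F1 = 2TP/(2TP+FP+FN), average precision as the stepwise area under the
precision–recall curve with exclusion of frames from normal VOIs,
Bland–Altman agreement on calcification angle/depth/thickness); the
stratified grouped 5-fold cross-validation protocol with a 4-way held-out
rotation; and a synthetic polar phantom generator with ground truth, so
every stage is testable without clinical data.

## Worked example

```r
library(octsubset)

cfg      <- phantom_config(n_frames = 30L, seed = 7L)
pullback <- generate_voi(cfg)                 # synthetic calcification VOI
pullback
#> <polar_pullback> 30 frames of 400 x 496 (r x theta), label: calcification

frames <- preprocess_voi(pullback)            # align, crop, denoise

equal_spacing_indices(length(frames), 1/10, voi_id = "voi_000")
#> <sampling_plan> voi: voi_000, method: equal_spacing, ratio: 0.1, 3 frames
#>  selected (0-based): 0 10 20

plan <- clustering_sample(frames,
                          sampler_config(ratio = 1/10, seed = 1L),
                          voi_id = "voi_000")
plan
#> <sampling_plan> voi: voi_000, method: clustering, ratio: 0.1, 3 frames
#>  selected (0-based): 8 22 29
str(plan$details)
#> List of 3
#>  $ pca_dim     : int 5
#>  $ ae_final_mse: num 0.00328
#>  $ medoid_cost : num 0.802
```

At a one-tenth ratio both selectors return 3 of the 30 frames. Equal
spacing walks the stack at stride 10; clustering picks the three frames
whose deep-feature representations are cluster medoids — here frames 8, 22
and 29, spread over distinct lesion configurations rather than distances.
`ae_final_mse` is the autoencoder's mean per-pixel squared reconstruction
error on the VOI (its quality gate is 0.03), `pca_dim` the retained feature
dimension, and `medoid_cost` the summed feature-space distance of frames to
their medoids.

The selected frames (plus every frame, as the baseline) feed
`train_segmenter()`, and `run_seven_model_comparison()` /
`run_fewer_vois_experiment()` reproduce the full multi-model protocol on a
phantom dataset; see the vignette in `vignettes/` for the methods and the
experiment design, and `inst/cli/octsubset.R` for a shell-level interface
(`phantom`, `preprocess`, `select`, `evaluate`).

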
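---
title: "CT-specific segmentation with ctseg: models, augmentation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-specific segmentation with ctseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctseg)
```

## The problem

Computed tomography poses two difficulties for convolutional segmentation
that ordinary image pipelines ignore. First, CT voxels live on the
Hounsfield scale — a calibrated radiodensity map with air at about
−1000 HU, water at 0 HU and cortical bone up to about 2000 HU — so absolute
grey values carry tissue identity, and the clinically relevant contrast
occupies a narrow sub-range of a very wide dynamic range. Second,
acquisitions are confined to a region of interest, so the number of slices
and the slice thickness vary strongly between cases. A model that is
accurate *on average* but erratic on atypical volumes is unusable inside an
automated analysis chain, where gross failures go unnoticed; the quantity
to control is therefore the *standard deviation* of the volume-wise Dice
score, not just its mean.

`ctseg` implements a CT-aware pipeline around this goal: windowing and
normalisation that mimic the radiologist's reading workflow, a CT-specific
augmentation (CTIA) operator family, a compound Tanimoto/crossentropy loss
for imbalanced voxel classes, modified U-Net and mixed-scale dense (MS-D)
backbones in 2D and 3D, slice-count-sorted cross-validation, and a stacked
ensemble. A synthetic phantom generator supplies HU-calibrated test data so
every stage is verifiable without clinical downloads.

## Preprocessing

`preprocess_case()` applies, in order:

1. **Percentile windowing.** Voxels are clipped to the (0.6, 0.99)
   percentile range of the intensity distribution — an organ-focused window
   comparable to what a radiologist would select. Quantiles use the
   linear-interpolation definition (R type 7) so independent
   implementations agree exactly. Windowing is per volume by default; a
   cohort scope is available.
2. **Z-score normalisation** with pooled mean/standard deviation taken from
   a *random subset* of windowed volumes (default at most 10 cases),
   mirroring the clinical situation in which only part of the data exists
   before training begins.
3. **Random slice sampling to 16 slices**, restricted to slices containing
   foreground during training (background slices are not scored at test
   time either). Short volumes are re-sampled with replacement rather than
   interpolated. Because the selection is random per epoch, repetition
   yields a free augmentation effect.
4. **In-plane downsampling to 128×128** by area averaging for intensities
   and nearest-neighbour for labels (no label bleeding, no new classes).

At inference (`predict_volume()`) no slice sampling or augmentation is
applied: 2D models run over every slice, 3D models over 50%-overlapping
16-slice slabs with uniform probability averaging.

## CTIA augmentation

`augment_batch()` fires on 90% of training batches for 2D models and 80%
for 3D models, applying operators in the fixed order rotation → patch →
slice skip/interpolation → CWVRS → noise (spatial before intensity, so
intensity statistics are computed on the final geometry):

* **Rotation** by one shared angle per volume in ±16° (a patient rotates
  rigidly); bilinear for intensities, nearest-neighbour for labels,
  exposed corners filled with the post-window background value.
* **Random patch extraction** with a single shared in-plane offset.
* **Slice skipping** removes up to 2 non-adjacent interior slices
  (simulating thicker effective spacing); **slice interpolation** inserts
  up to 2 voxel-wise midpoint slices whose label plane is copied from one
  parent. The two are mutually exclusive per volume.
* **CWVRS** (cluster-wise voxel intensity range shift) perturbs predefined
  tissue windows — soft tissue (−150, 250) HU, lung (−1000, −300) HU, bone
  (200, 2000) HU — by a shift of at most ±20 HU and bound changes of at
  most ±10% of the window width, then linearly remaps in-window voxels.
  Voxels outside every window stay bit-identical. Applied to 20% of
  volumes. When augmentation runs after normalisation the window table and
  shift bound are passed through the same z-score transform.
* **Gaussian noise** (σ = 0.05 in normalised units by default).

Every operator preserves the image/label pairing under identical geometry,
never introduces a label value absent from its input, and reduces to the
exact identity when its magnitude parameter is zero — these are tested
properties, not aspirations.

The CWVRS magnitudes (±20 HU, ±10% width) are package defaults chosen small
relative to typical window widths of several hundred HU; the window table
itself is configurable because appropriate presets depend on the organ of
interest.

## Loss and evaluation

Training minimises `alpha·L_Tanimoto + beta·L_CE` with α = 0.6, β = 0.4.
The Tanimoto term is computed per class as

    L_c = 1 − (⟨p, y⟩ + s) / (‖p‖² + ‖y‖² − ⟨p, y⟩ + s),   s = 1e−5,

then averaged unweighted over classes: treating classes independently is
what makes the loss robust to the severe foreground/background imbalance of
organ segmentation, and the smoothing constant prevents a maximal error
when a class is absent from a sample (the empty-class term becomes s/s,
i.e. zero loss). The sum-of-squares norms follow the formula as printed;
crossentropy probabilities are clamped at 1e−12 for log stability.

Evaluation uses the Dice score per class and volume,
`2⟨p,y⟩/(‖p‖²+‖y‖²)`, with the 0/0 case (class absent from both volumes)
defined as 1 and flagged so reports can exclude it. `aggregate_dice()`
reports both a two-level aggregation (volumes within fold, then across
folds — the headline) and a pooled-over-volumes variant, because "averaged
over volumes and folds" admits both readings; the "total" row is the
class-averaged Dice per volume, with the foreground-pooled variant
available from the raw scores.

## Backbones

Both architectures receive the same two modifications: batch normalisation
is replaced by instance normalisation (well-defined at batch size 1, which
3D training requires) and all activations are LeakyReLU with slope 1e−2.

* **U-Net**: a plain encoder–decoder with skip connections, double
  conv-IN-LReLU blocks, 2× max pooling and nearest-neighbour upsampling;
  depth 4 and base width 24 by default.
* **MS-D**: densely connected single-width dilated 3×3 convolutions at
  fixed resolution (no pooling), dilation cycling 1..10, 40 layers by
  default, and a final 1×1 convolution over all accumulated features.

The exact topology variant behind the named modifications is not pinned
further, so the package implements a standard U-Net plus those two changes;
network sizes are configuration, with much smaller values used in tests.

The layers are implemented directly on R arrays: convolutions as sums of
zero-padded spatial shifts, each reduced to one BLAS matrix product, with
hand-derived backward passes verified against numerical differentiation for
all four backbone variants. ADAM uses the standard proposed parameters
(learning rate 1e−3, β₁ = 0.9, β₂ = 0.999). Training batches are 28 slices
for 2D models and 1 volume for 3D models; an "epoch" is a fixed number of
batches because sampling is with replacement.

A note on determinism: every stochastic component draws from isolated,
seeded RNG streams, argmax tie-breaking is fixed to the first class, and
the package pins OpenBLAS to one thread at load (`set_blas_threads()`),
because threaded matrix-product reductions are not bitwise reproducible and
would break the identical-trajectory contracts the tests assert.

## Cross-validation and ensembling

`assign_folds()` deliberately does *not* balance folds: cases are sorted by
slice count (ties: slice thickness, then identifier) and cut into k
contiguous blocks. Validation volumes therefore differ systematically from
the training volumes — the worst-case scenario a deployed model faces.

`stacked_predict()` combines a set of 3D MS-D binary localisers with a set
of 2D U-Net multi-class classifiers (top-5 by validation Dice via
`select_top_k()`, ties broken by training order). Member probabilities are
averaged within each set. Because the stacking rule itself is a design
choice, three combiners are provided: `mask_gate` (default — background is
`max(M_bg, 1−B)` and foreground mass is redistributed proportionally to the
multi-class map; encodes the division of labour directly and needs no extra
training), `prob_product` (independent-evidence product fusion), and
`meta_learner` (a per-voxel multinomial combiner fitted on validation
cases — the "learned balance" reading). None is claimed to be the canonical
rule; `mask_gate` is the default because it is parameter-free and its
contracts (zero binary foreground ⇒ all background; consistent members ⇒
identity) are exactly testable.

## The phantom generator

`generate_phantom()` builds ellipsoidal geometry — a soft-tissue body in
air, one organ, and with probability 0.7 a tumour blob intersecting the
organ — with Gaussian intensity clusters: air −1000 ± 15 HU, body +40 ± 12,
organ +60 ± 10, tumour +100 ± 12, plus σ = 8 HU acquisition noise, stored
as integers in the 12-bit CT range [−1024, 3071]. Slice counts and
thicknesses vary per case so slice-sorted folds are non-degenerate. The
organ/tumour contrast is kept deliberately small so that windowing
decisions matter. `perturb_cohort()` applies a global affine intensity map
(vendor/patient calibration shift) to build distribution-shifted test sets.

What the phantom does *not* emulate: anatomy (shapes are ellipsoids),
partial-volume effects, beam hardening, reconstruction kernels, metal
artefacts, or spatially correlated noise. Passing tests on phantoms
demonstrates that the machinery is correct and that the robustness
mechanisms act in the intended direction; it does not certify clinical
performance.

## Scaled-down experiments

Full-scale training of eight model variants on clinical challenge data
requires GPUs and external downloads; the package's own experiments are
desk-scale by design, and the sizes below are the package's standing study
conditions:

* **Overfit smoke test**: a 6-slice 24×24 binary batch from a zero-noise
  phantom; U-Net (depth 2, width 6) and MS-D (12 layers, dilations 1..6)
  must drive the compound loss below 0.05 within 500 ADAM steps.
* **Robustness experiment**: 20 phantoms (48×48 in-plane, 10–40 slices),
  2 slice-sorted folds, tiny 2D U-Nets (depth 2, width 6, 24×24 working
  size, 8-slice stacks), 400 steps per fold, CTIA versus no augmentation,
  evaluated on a test cohort shifted by +60 HU and scaled by 1.05. The
  assertion is directional: the standard deviation of volume-wise Dice for
  the CTIA model must not exceed that of the unaugmented model at the
  frozen seed.

Numerical edge cases are handled as follows: degenerate pooled statistics
(zero variance) are an error rather than a silent division; CWVRS resamples
a perturbation up to 20 times if it would invert a window; stacks too short
for slice skipping pass through with a notice; the 3D inference slab at the
volume end is edge-replicated; and `dice_score` flags its 0/0 convention.

## Limitations

* No DICOM ingestion and no spatial resampling: the framework operates in
  voxel space (NIfTI in/out), assuming per-slice operations as the
  preprocessing defines them.
* The dense-array engine is CPU-bound and intended for method development,
  testing and small studies, not for full-resolution clinical training.
* The supplementary intensity-window presets of the original clinical
  pipelines are not public; the defaults here are standard radiology
  ranges and should be adapted per application.
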
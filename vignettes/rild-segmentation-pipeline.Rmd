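---
title: "Five-class RILD tissue segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-class RILD tissue segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiation-induced lung damage (RILD) after radiotherapy for lung cancer
produces a spectrum of parenchymal change visible on CT: from normal
aerated lung through ground-glass opacity (GGO), GGO with overlaid
reticulation, near-solid tissue, up to homogeneous dense consolidation.
Classical global scoring systems assign one grade per scan and cannot
describe where, and as what pattern, damage appears. `rildseg` implements a
voxel-wise alternative: every lung voxel is assigned one of five tissue
classes ordered by increasing density (Class 1 normal lung ... Class 5
consolidation), using an ensemble of 2D U-Nets applied slice by slice, and
evaluated with a pooled ("global") Dice coefficient.

Clinical RILD cohorts of this kind are not openly downloadable, and
study-scale training needs GPUs. The package therefore ships a synthetic CT
phantom generator that reproduces the *statistical structure* the pipeline
has to cope with — five-class density ladder, severe class imbalance,
heterogeneous voxel spacing, lesions growing over follow-up time points —
so that every stage is exercisable and testable end-to-end on a desktop
CPU.

## The pipeline

1. **Input.** Per scan: an HU-valued CT volume, a binary lung mask (manual
   in the intended application; the package never segments lungs itself)
   and, for training/evaluation, a voxel-wise label map with classes 1-5
   inside the lung and a 0 sentinel outside. All grids are NIfTI;
   geometry mismatches between the three files are hard errors.
2. **Preprocessing.** Anatomy outside the lungs is masked to air
   (-1000 HU). Each axial slice is cropped to the pooled lung bounding box
   and fitted to a fixed rectangular network input, (288, 384) at study
   scale. Original resolution is kept whenever the box fits (symmetric
   padding); otherwise one isotropic scale factor `s = min(target/bbox) <
   1` shrinks it — never anisotropic resampling, so aspect ratio is
   preserved. Intensities are windowed from [-1000, 100] HU onto [0, 1];
   labels are resampled nearest-neighbour.
3. **Slice filtering.** Lung volume is overwhelmingly Class 1 (about 94%
   pooled in the regime the phantom emulates). Training uses only slices
   in which at least 1% of lung tissue carries classes 2-5 (ties at
   exactly 1% retained; the fraction's denominator is the slice's lung
   area). Filtering necessarily raises the pooled pathology share of the
   training pool; how much depends on how axially concentrated lesions
   are (in the default phantom, whose lesions span many slices, the shift
   is modest). The filter applies to *training sample construction only*:
   inference
   and evaluation always run on every lung-containing slice, since test
   volumes must be fully labelled.
4. **Networks.** A canonical depth-4 2D U-Net: two 3x3 convolutions per
   level, each followed by instance normalisation and ReLU; 2x2 max-pool
   down; nearest-upsample + convolution up with skip concatenation; a 1x1
   convolution to five class channels with a softmax head. Filter widths
   are f, 2f, 4f, 8f, 16f. The forward and backward passes are written
   natively (C++ via Rcpp/RcppArmadillo, im2col convolutions with analytic
   backprop verified against finite differences) — no external
   deep-learning runtime is involved.
5. **Losses.** Three per-voxel training objectives over lung voxels only:
   frequency-weighted cross entropy (WCE), multiclass soft Dice (DC), and
   Lovasz-softmax (LV), the convex Lovasz-extension surrogate of
   `1 - IoU`. On hard predictions LV equals the mean of `1 - IoU` over
   classes present in the target, which the tests verify exhaustively on
   small instances.
6. **Ensembling.** The stage-one (draft annotation) preset is three
   networks, WCE at the smaller width and LV at both widths; the stage-two
   preset crosses all three losses with both widths (six networks).
   Members are fused by summing pre-softmax logit scores channel-wise and
   only then taking the per-voxel argmax, so each member contributes its
   confidence, not just its label. No other postprocessing is applied
   beyond re-imposing the lung mask.
7. **Evaluation.** Per class, `DSC = 2TP / (2TP + FP + FN)` with counts
   pooled over every lung voxel of every scan of the set before the ratio
   ("global Dice"). Pooling avoids the distortion of averaging per-scan
   scores when a rare class has only a handful of voxels in some scans; a
   constructed two-scan example in the tests shows pooled 200/220 = 0.909
   against a per-scan mean of 0.545. A class absent from both predictions
   and truth across the whole set is reported as missing (`NA`), never as
   0 or 1. Confusion matrices, patient-level 5-fold cross-validation with
   `mean ± 1.96·sd/√K` summaries, voxel-wise disagreement maps and the
   refinement/qualitative-score bookkeeping complete the reporting.

## The phantom generator

Each case embeds two ellipsoidal lungs in a soft-tissue body (≈ +30 HU) on
an air background. Inside the lungs a spatially smooth "damage" field —
correlated Gaussian noise plus a focal bias centred in one lung per
patient, since RILD is a local effect tied to the treated side — is
thresholded by quantiles so that realised class-volume fractions match the
configured targets exactly, with the densest class at the damage core.
Default targets are (0.937, 0.035, 0.003, 0.005, 0.020), mirroring the
pooled imbalance regime of the intended application. Lesion volume is
scaled per time point by (1/3, 2/3, 1, 4/3, 5/3) across the five scans of
a patient — linear growth with mean 1, so cohort-pooled fractions still
match the targets.

Voxel HU is `mean_c + spread_c × noise` with a shared unit-variance
correlated noise field; the per-class means (-800, -550, -450, -200, +40)
and spreads (60, 60, 60, 60, 50 HU) are declared generator parameters —
plausible CT physics with monotone separation but real overlap between
neighbouring classes, chosen once and not fitted to anything. Class 3
additionally carries a high-spatial-frequency sinusoidal line texture
(amplitude 80 HU, period 3 voxels, random phase) as a reticulation
analogue. Per-volume spacing is drawn from axial 0.57-1.40 mm and slice
thickness 0.7-5 mm, so a cohort is resolution-heterogeneous. A single
integer seed determines every emitted voxel bit-for-bit.

What the phantom deliberately does **not** model: airway/vessel/diaphragm
anatomy, dose distributions, breathing motion or reconstruction-kernel
artefacts. Passing the end-to-end tests therefore demonstrates that the
pipeline's machinery (filtering, geometry, losses, fusion, metrics)
works and that the ensemble can learn a five-class density problem with
realistic imbalance — not that it reaches clinical-data accuracy.

## Numerical and design choices

* **Voxel order** is (z, y, x) internally; axial slices are fixed-z planes
  with 288 rows (anterior-posterior) by 384 columns (left-right) at study
  scale, since axial lungs are wider than deep. NIfTI files keep the
  conventional (x, y, z) layout.
* **Sentinel** for outside-lung voxels is 0, the de-facto background
  convention, keeping stored classes 1-5 aligned with their names.
* **Masked fill** is -1000 HU (air): the least informative physical value.
  The **intensity window** [-1000, 100] HU is fixed rather than
  percentile-based, for robustness to protocol and contrast variation.
* **WCE weights** are inverse pooled class frequencies normalised to mean
  1, with a configurable cap (default 100) for a class that never occurs,
  which warns rather than producing an infinite weight.
* **Soft Dice smoothing** is 1, applied to numerator and denominator, so
  perfect predictions score exactly 0 and absent classes cannot produce
  0/0. **Lovasz-softmax** averages over classes present in the target, the
  convention of its reference formulation, making it robust to absent rare
  classes.
* **Training** uses Adam (default rate 1e-3; the desk-scale studies use
  1e-2), batch size one slice, seeded shuffling, optional early stopping
  on a validation set, and a hard abort on non-finite loss. Initialisation
  is He-normal from the config seed; identical seeds reproduce identical
  weights bit-for-bit.
* **Ties** in the per-voxel argmax resolve to the lowest class index;
  slice retention at exactly the 1% threshold retains the slice ("at
  least 1%").
* **Crop inversion** maps every source voxel to the network pixel it was
  forwarded to, so each lung voxel receives exactly one label even at
  s < 1; at s = 1 the mapping is an exact translation and label
  histograms are conserved.
* **Input channels**: the presets use the single windowed slice. An
  odd number of adjacent slices can be stacked as channels via
  `make_samples(channels = )` and `net_config(in_channels = )` for
  experiments; no preset enables it.

## Problem sizes in the shipped studies

The packaged end-to-end study (`scaled_down_study()`, also what
`scripts/acceptance.R` runs) uses a 6-patient x 5-time-point cohort on
48 x 64 x 96 grids, network input (48, 80) at original resolution, widths
4 and 8 for the six stage-two members, eight epochs over at most six
filtered slices per volume, and holds out two patients for pooled-Dice
evaluation. Cross-validation protocol checks use a 10-patient x
2-time-point cohort with a deliberately minimal single-network
configuration — the fold bookkeeping under test is identical at any
network size. These sizes are the package's chosen desk-scale defaults;
all of them are arguments, and study-scale values ((288, 384) inputs,
widths 32/64, full slice sets) are a single configuration change.

## Known limitations

* The phantom's classes are separable mainly by intensity and one texture;
  real RILD patterns overlap far more, and reticulation is a 3D structure
  only caricatured by in-plane stripes. Desk-scale Dice values on phantoms
  say nothing quantitative about clinical data.
* The slice-wise 2D design ignores through-plane context by construction;
  adjacent-slice channels are available but unexplored here.
* Training is batch-size-one without augmentation; at study scale both
  would typically be revisited.
* `crossval_run` retrains the full ensemble per fold; at study scale this
  is the dominant cost and would be distributed.
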
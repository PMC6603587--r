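---
title: "Methods: patch-based CNN detection of cerebral small-vessel lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based CNN detection of cerebral small-vessel lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model
and its assumptions, the parameters that matter, what the synthetic
phantom does and does not establish, and the design choices made where
the design was genuinely open.

## The problem

Cerebral small-vessel disease shows up on T1-weighted turbo-spin-echo
brain MRI as focal hyperintense lesions, by definition smaller than
1.5 cm. They occupy a minute fraction of each 512×512 slice, so
whole-image classification is hopeless: the lesion signal is drowned
by the other classes. The pipeline therefore (a) removes everything
that cannot contain a lesion (background, cranium), (b) classifies
small 7×7 patches independently, and (c) reassembles the patch
decisions into a per-pixel label map from which lesions are measured.

Four classes are used throughout: 0 non-brain (black), 1 normal
brain (green), 2 central brain (blue), 3 lesion (red); the RGB colors
are the annotation convention for ground-truth images.

## Brain extraction

Six rule-based steps: binarize; delete the maximum-area connected
component (the cranium shell, which is the brightest large structure
on T1); inverse-binarize at the same threshold to get the
sub-threshold interior; union the residual bright structures with
that interior, restricted to the intracranial region; median-filter;
measure.

Numerical and design choices:

* **Threshold.** Otsu's criterion is the parameter-free default, but
  it maximizes between-class variance over the *whole* histogram. On
  images with a large dark background (the phantom; most MRI with
  wide fields of view), the dominant split is background-vs-tissue,
  not tissue-vs-cranium, and the "largest component" would then be
  the brain itself. Clinical practice for this step was manual
  per-image tuning; this package keeps Otsu as the default and uses a
  fixed threshold midway between the brain and skull class means
  (`phantom_extraction_threshold()`) wherever the phantom's
  intensities are known. The threshold actually applied is recorded
  on the result.
* **Step-4 restriction.** The raw union of steps 2 and 3 includes the
  exterior background (equally sub-threshold). A centroid-in-the-
  cranium-box rule does *not* disambiguate: the exterior surrounds
  the head symmetrically, so its centroid also lies near the image
  centre. The rule used instead is containment: keep components
  lying entirely in the strict interior of the removed cranium's
  bounding box. The exterior always touches the image border or
  spills outside the box and is dropped; intracranial components are
  strictly inside. This is the minimal disambiguation that is correct
  by construction on ring-shaped crania.
* **Connectivity 8** (default): 4-connectivity can split thin
  diagonal sections of the skull ring into separate components.
* **Median kernel 3×3**, the smallest noise-removing kernel. Note a
  strict binary median erodes isolated pixels *and* the four corner
  pixels of any solid rectangle (4 of 9 neighbors); that is the
  mathematically correct behavior and what the tests assert.
* **Degenerate inputs** (constant images, empty masks) raise typed
  errors rather than returning empty results — fail loudly in a
  clinical-adjacent tool.
* **Ties** for the maximum-area component resolve to the component
  first encountered in a row-major scan, and the tie is flagged.

## Patching

Non-overlapping 7×7 tiling (stride = patch size), padding with zeros
on the bottom/right only so the top-left origin is stable for
coordinate reporting; `ceiling(512/7) = 74`, hence 74 × 74 = 5476
patches on the nominal raster, padded to 518×518.

Ground-truth patch labels use the `any_lesion` rule by default: a
patch is a lesion patch as soon as one lesion pixel falls in its
footprint, otherwise the majority class with ties broken by clinical
priority 3 > 2 > 1 > 0. Lesions are rare and small; a plain majority
vote would erase every sub-patch lesion and the classifier would be
trained to ignore exactly the class of interest. The majority rule is
available for comparison.

## The classifier

The default CNN has seven weighted/pooling layers on the 7×7 input:

```
conv 3×3, 16 filters (valid)  ->  5×5×16
conv 3×3, 32 filters (valid)  ->  3×3×32
maxpool 2×2                   ->  2×2×32
conv 3×3, 64 filters (same)   ->  2×2×64
fc 128 -> fc 64 -> fc 4 + softmax
```

The layer inventory (three convolutions for feature extraction, one
pooling stage to shrink the map, three fully connected layers, 4-way
softmax) is fixed; the per-layer padding was an open choice, and
valid convolutions before pooling were chosen because zero-padding a
7×7 patch mostly manufactures border features and triples the CPU
cost. ReLU activations, He-normal initialization. The MLP baseline
flattens the 49 pixels into the same fully connected head
(49→128→64→4).

Training: mini-batch SGD, batch 128, learning rate 0.01, momentum
0.9, cross-entropy, 180 epochs by default (the published iteration
count). Everything is seeded — weight initialization from the config
seed, shuffling from seed + 1 — so training is bit-reproducible on a
platform. Inputs are explicitly rescaled from native integer range to
[0, 1]; I/O stays lossless. Inverse-frequency class weights exist but
are off by default: the imbalance is real, and silently reweighting
would change the comparison semantics.

Implementation note: convolutions run as im2col matrix products. The
gather/scatter between the activation layout and the im2col layout is
compiled (Rcpp); the arithmetic is BLAS. Prediction breaks ties in
the softmax argmax toward the *higher* class id, i.e. lesion-favoring.

`segment_slice()` skips inference for patches wholly outside the
brain mask (assigned class 0 directly), both for speed and so that
non-brain areas can never produce lesion calls.

## Evaluation

The published confusion tables are *rate-valued*: each cell is a
fraction of the positive total (95 training / 86 testing instances)
or negative total (110 / 120). The summary statistics reproduce the
published tables only when

* precision is computed on those rates, `tp_rate / (tp_rate +
  fp_rate)` — count-based precision gives 94/96 ≈ 0.979167 where the
  table prints 0.981956315; and
* recall is computed exactly as printed, `FN / (TP + FN)` — the miss
  rate, not sensitivity. Whether that was intended is unknowable from
  the source; both forms are provided (`paper_recall()`,
  `standard_recall()`), clearly named, and the reproduction uses the
  as-printed form.

All metric arithmetic is exact: fractions are integer
numerator/denominator pairs (reduced by gcd after every operation, so
magnitudes stay far below 2⁵³ even though they are held in doubles),
and rendering to 9 decimals uses half-even rounding computed
digit-by-digit in integer arithmetic. This removes any float-ordering
nondeterminism from the acceptance comparisons.

The published summary tables print identical YOLO1 and YOLO2 columns,
both consistent with YOLO2's confusion cells and not YOLO1's. The
reproduction (`reproduce_report_tables()`) maps both columns to the
YOLO2 cells, reports every cell as matching, and separately reports
what YOLO1's own cells would give (`yolo1_discrepancy`) instead of
silently "fixing" the source.

## The phantom: what it emulates, what it does not

`generate_slice()` draws a bright cranium ring (outer radius 0.46 of
the image), a dark CSF-like gap, a brain disk, a dark central
ellipse (ventricle-like, semi-axes 0.32 and 0.16 of the brain
radius), and 0–4 hyperintense lesion disks of 2–14 mm diameter with a
Gaussian-profile edge taper, then adds Gaussian noise (σ = 8) and
clips to [0, 255]. Default class means: background 5 < central 60 <
brain 120 < lesion 200 < skull 230 — the T1-like brightness ordering.
The pixel spacing defaults to a fixed 256 mm field of view
(256/image_size mm per pixel, 0.5 mm at the nominal 512), so
millimetre-valued lesion sizes keep their physical meaning when the
raster is scaled down for fast tests. The skull is labeled class 0:
the 4-class scheme has no separate skull class.

Datasets split 205/205/206-proportionally (largest-remainder rounding
for other n), stratified by lesion presence, with per-slice seeds
derived from the master seed.

What a green phantom test establishes: the pipeline's mechanics —
extraction steps, tiling, learning machinery, reassembly, metrics —
are correct and deterministic, and the classifier can learn a
hyperintensity signature under noise and class imbalance (patch-level
lesion prevalence is below 5 %, as in the clinical regime). What it
does not establish: performance on real tissue texture, partial
volume effects, Rician noise, bias fields, or anatomical variability.
Published real-data accuracies (98.57 % / 98.52 % etc.) are therefore
*not* reproduced — the clinical dataset is private — and are replaced
by property-based floors on the phantom (≥ 95 % validation patch
accuracy, ≥ 60 % lesion recall, CNN ≥ MLP over 5 seeds); a recent run
gave 99.6 % / 88.5 % and CNN 0.756 vs MLP 0.118 mean lesion recall.

## Lesion reporting

Per-slice: one record per 8-connected lesion component — centroid,
tight bounding box (1-based, closed), pixel and mm² area, maximum
pairwise pixel distance × spacing as the diameter (computed exactly
via the convex hull), and the < 15 mm small-vessel flag. The flag
never suppresses a detection: the threshold is a definition, not a
filter, and that decision belongs to the clinician. Records are
ordered by area descending, then centroid row-major.

Across slices: lesions whose footprints touch (26-connectivity on the
stacked voxel grid) merge into 3D groups; group volume is the sum of
member areas times the inter-slice spacing, default 4.4 mm = 3.4 mm
slice thickness + 1.0 mm gap. The acquisition never states the
in-plane pixel spacing, so every mm-valued output takes a
user-supplied spacing (documented default 0.5 mm/px). The "3D
display" output is realized as this quantitative stacked report plus
per-slice overlays, not an interactive renderer.

## Conventions and I/O

All matrices are `[row, col]`, 1-based, row 1 at the top; bounding
boxes are closed intervals. (A 0-based half-open convention was
considered and rejected: it fights every R indexing operation, and
the package reports coordinates to R users.) Intensities stay in
native integer range end to end; the classifier's [0, 1] rescale is
the single explicit normalization. Slices are read/written as 8-bit
grayscale PNG or NetPBM PGM (ASCII and binary read, ASCII write);
label maps as RGB PNG/PPM using the 4-color convention with a decode
tolerance of 16 gray levels for hand-drawn annotation edges. DICOM
and TIFF are recognised extensions but unsupported in this build (no
reader in the dependency footprint); single-frame DICOM support would
slot into `read_slice()` without interface changes.

## Known limitations

* The phantom's structures are analytic disks/ellipses; no tissue
  texture or acquisition physics.
* Only 3×3 convolutions and 2×2 pooling are implemented — enough for
  the fixed 7-layer family, not a general deep-learning framework.
* Training is CPU-bound by design (the published model also ran on
  CPU to keep resource use minimal); a 180-epoch run on the reduced
  phantom takes a few minutes of one core.
* 10-fold cross-validation is provided as a split utility
  (`kfold_split()`); the published per-fold protocol beyond the split
  itself is unspecified and not reconstructed.
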
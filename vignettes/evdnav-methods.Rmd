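---
title: "Methods: models, phantoms and numerical choices in evdnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, phantoms and numerical choices in evdnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evdnav)
```

`evdnav` implements the computational half of an augmented-reality
navigation workflow for extra-ventricular drainage (EVD): everything that
turns a CT head series and a stream of tracked instrument positions into a
recommended ventricular target, a displayed DICOM slice, a trajectory and a
color-coded alignment cue. The AR rendering and optical tracking themselves
are out of scope; simulated pose streams stand in for the tracker. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where the procedure left room.

## Coordinate model

A DICOM series becomes a `voxel_volume`: an `(Num_x, Num_y, Num_z)`
intensity grid with per-axis physical spacings in mm. One convention is
used everywhere:

* **x** — patient left to right (slice image width),
* **y** — the DICOM stacking axis (slice numbers),
* **z** — inferior to superior (slice image height).

The head-space origin sits at the lower-left of the head, slice indices
are 1-based at every public interface, and voxel `(i, j, k)` is centred at
`origin + (c(i, j, k) - 0.5) * spacing`. Anisotropic voxels are kept
as-is; nothing is resampled.

## Automatic scanning and the slice-index map

`scan_reference_points()` marches a virtual plane perpendicular to each
axis inward from either side in steps of `sweep_step_mm` (default 0.1 mm)
and reports the first position whose intersection with the object is
non-empty. The six collision coordinates are the reference points; for any
object they equal the axis-aligned bounding extremes of the occupied set
to within one sweep step, which gives the brute-force oracle used in the
tests. Meshes use a triangle-span test; voxel occupancies treat the voxel
centres as the scanned point set.

From the six points, `derive_extents()` computes the per-axis extent
`Dis_a = max_a - min_a` and slice thickness `T_a = Dis_a / Num_a`.
`point_to_slice_indices()` then maps a tracked point `Ep` to
`raw_a = (Ep_a - min_a) / T_a` and the integer index
`floor(raw_a) + 1`, clamped to `[1, Num_a]`. Three decisions are worth
stating:

* the subtraction is grouped, `(Ep - RP) / T`, on all three axes;
* floor-plus-one makes every point inside slice `k`'s physical span map to
  `k`, so the centre of slice `k` always returns `k`;
* a component below the axis minimum raises an error instead of clamping —
  a scalpel tip outside the scanned head is a tracking fault the caller
  must see.

## Picking targets on slices

A surgeon's pick `(X_2D, Y_2D)` on slice `N_target` converts to head space
as

```
x = X_2D * I_X3D / I_dicomX2D
y = (I_Y3D / N_total) * (N_target - 1)
z = Y_2D * I_Z3D / I_dicomY2D
```

Pixel coordinates have their origin at the lower-left of the displayed
slice, matching the head-space origin; slice 1 anchors the `y = 0` plane,
so targets always lie on slice planes with no intra-slice interpolation.
The inverse map (`target_3d_to_2d()`) quantizes `y` with
`floor(y * N_total / I_Y3D) + 1`, the exact inverse on slice planes, and
snaps pixel coordinates to the integer grid when within `1e-6` px so that
integer picks round-trip with zero error.

## Target recommendation

Predicted per-slice masks are stacked into a volume and labeled with
26-connected components (`label_components()`), the 3D analogue of the
classic 8-connected 2D labeling; a per-slice 8-connected mode is provided
for comparison. The largest component wins, ties going to the smallest
label. Its voxel-coordinate mean, rounded to the nearest voxel with exact
halves toward the lower index (so the target is displayable on an actual
slice), is the recommended target; its stacking-axis index is the
predicted axis plane compared against the plane of a reference target to
give the scanning-plane error.

## The segmentation network

`build_unet()` constructs the U-Net: five resolution levels with
feature-map widths 32/64/128/256/320, two 3x3 stride-1 convolutions per
level, each followed by batch normalization and ReLU; 2x2 max pooling on
the way down; stride-2 2x2 transpose convolutions (also with batch norm
and ReLU, reading "each convolution layer" inclusively) and concatenating
skip connections on the way up; and a final 1x1 convolution with sigmoid
output thresholded at 0.5. Training (`train_unet()`) uses dice loss with
smoothing `eps = 1` in numerator and denominator, computed per map and
averaged over the batch, the Adam optimizer at learning rate 0.003, batch
size 20, and 30 epochs; the weights of the epoch with the lowest training
loss are kept, as no validation split is defined. Weight initialization is
He-style from a dedicated deterministic generator, with one addition: the
final-layer bias starts at the class-prior logit `log(0.03/0.97)`
(a ventricle occupies roughly 3% of a slice). Without it, a sigmoid that
starts at 0.5 everywhere makes early dice gradients fight the background
on heavily imbalanced masks, and at desk scale some seeds never recover
within 30 epochs.

`grouped_cross_validation()` splits at the patient level: sorted group ids
are divided into equally sized consecutive test folds (10 groups and 5
folds give 2 test groups and 8 training groups per fold, overridable by an
explicit assignment), so no patient contributes slices to both sides of a
fold.

The whole engine is implemented in compiled code inside the package
(im2col GEMM convolutions, hand-derived backward passes); every layer's
gradient is verified against central finite differences in the test suite
at tolerance 1e-4, and training is bit-reproducible given the seeds and a
fixed thread count.

## Trajectory guidance

`build_trajectory()` normalizes the entry-to-target segment;
`angle_deviation()` is the arc cosine of the clamped dot product between
the scalpel shaft and the trajectory. Guidance colors are green for
deviations up to 2 degrees, yellow up to 10, red beyond — the thresholds
are configurable because the procedure defines the colors but not the
cut-offs; boundaries are inclusive. Remaining depth is the signed
projection of `target - tip` onto the trajectory (negative on overshoot),
deliberately insensitive to lateral offset, which is reported separately
as the perpendicular distance from the planned line. `replay_guidance()`
applies all of this per sample of a tracked stream, taking the shaft
direction as entry-to-tip.

## Evaluation statistics

Pixel-wise sensitivity, specificity and accuracy come from exact confusion
counts; a metric with a zero denominator is reported as `NA`, never 0, so
averages cannot be silently biased. The stability statistic centres a
recorded position stream on its mean ("normalization"), takes each
sample's Euclidean distance from that mean, and reports the mean and SD of
those deviations, alongside raw per-axis SDs. For an isotropic Gaussian
jitter of scale sigma the mean deviation has the closed form
`sigma * sqrt(2) * gamma(2) / gamma(1.5) ~= 1.596 sigma`, the oracle used
in the tests. Boxplot summaries use linear-interpolation quartiles
(`quantile` type 7) with Tukey 1.5 IQR fences for outliers.

## The phantom family

Clinical CT and trained clinical weights are not shipped; every stage is
instead exercised on synthetic head phantoms with known ground truth.

A phantom is a stack of concentric ellipsoids on a default 64 x 48 x 64
grid with 1.0 x 1.5 x 1.0 mm voxels: scalp surface, 2 mm skin layer, a
4 mm skull shell, brain tissue, and one or more ellipsoidal ventricle
blobs (defaults near-centre, semi-axes about 8-11 mm). Tissue intensities
are specified in Hounsfield units (air -1000, CSF 5, brain 35, scalp 60,
bone 800) with Gaussian detector noise of 5 HU added in HU, and the
result is then brain-windowed (level 40, width 80) onto an 8-bit display
scale — the representation a clinical ventricle-segmentation pipeline
consumes, with air and bone clipping flat exactly as on a windowed
workstation image. Early development used raw full-range stored values
instead; after per-volume min-max normalization that leaves only ~1.7%
CSF-to-brain contrast and the desk-scale network cannot converge in 30
epochs, so the windowed representation was adopted as the realistic
emulation target. The truth object records the exact ventricle mask, the
largest blob's centroid (analytically countable because blobs are
validated to be disjoint), its stacking-axis slice, and a closed
octahedron-subdivision scalp mesh whose convexity gives plane-sweep
scanning a closed-form oracle.

`phantom_slice_dataset()` emulates the clinical training database: each
group is one synthetic patient with its own randomized ventricle geometry
(position within +/-6 mm, semi-axes 5-13 mm), contributing 25 stacking-axis
slices, 80% through the ventricle and 20% ventricle-free — drawn only from
head-containing planes, since every slice of a patient's head series shows
anatomy. Simulated tracking streams add isotropic Gaussian jitter to a
fixed marker position at 1 Hz for one minute; the default jitter SD of
0.048 mm is chosen so the expected mean deviation (1.596 sigma) reproduces
the sub-0.1 mm stability regime of a well-anchored image-target tracker.

What passing tests on these phantoms do and do not show: they verify the
geometry chain (scanning, slice mapping, display conversion) essentially
exactly, and they show the segmentation/recommendation machinery learns
and localizes windowed-CT-like ventricles from grouped patients. They do
not certify performance on clinical anatomy — real ventricles are not
ellipsoids, real CT has partial-volume and beam-hardening structure the
phantom omits, and real trackers drift non-isotropically.

## Problem sizes and reproducibility

The shipped checks run at desk scale, chosen to keep the whole suite
reproducible on a single CPU: a channel-scaled network (widths divided by
8) on 64 x 64 slices, 10 phantom patients x 25 slices (200 training, 50
held-out), 30 epochs — about two minutes per seed — plus 100-phantom
geometry sweeps and 1000-pick round-trips. At these sizes the 3-seed
majority criterion (training dice >= 0.8, held-out >= 0.7) passes with
dice above 0.97 on all seeds. All randomness flows through explicit seeds:
phantom geometry, noise, slice sampling, weight initialization and batch
shuffling are each separately seeded, and two runs with the same seeds are
bit-identical.

## Known limitations

* Only uncompressed single-frame DICOM is read or written; no multi-frame
  files, compressed transfer syntaxes, oblique gantry tilt or PACS access.
* The slice-thickness model ties `T_a` to the scanned object's extent, so
  the mapping assumes the series is cropped to the head (use
  `crop_volume()` for phantoms embedded in larger grids).
* Whether the deployed system floored or rounded fractional slice values
  is unknowable from the procedure text; floor-plus-one is this package's
  documented choice.
* Whether the largest ventricular component should be taken in 3D across
  slices or in 2D per slice is ambiguous; both modes exist and 3D is the
  default.
* The U-Net runs on CPU only and at clinical widths is far slower than a
  GPU implementation; it is intended for method-faithful experiments, not
  production inference speed.
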
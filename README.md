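# evdnav

Computational core of an image-guided, augmented-reality navigation
pipeline for extra-ventricular drainage (EVD) neurosurgery. EVD places a
catheter into a brain ventricle to drain cerebrospinal fluid; an AR
navigation system must know where the ventricle is, which DICOM slice the
surgeon's instrument is pointing at, and how far off the planned
trajectory the scalpel currently is. `evdnav` implements that chain for R
users — methods researchers and engineers evaluating image-guided
navigation — end to end, with synthetic head phantoms so every stage is
testable without clinical data:

* **Volume I/O** — read/write single-frame CT DICOM series into a voxel
  volume with per-axis slice counts and spacings; slice extraction and
  min-max normalization.
* **Automatic scanning** — sweep axis-perpendicular planes at a virtual
  head object to find the six reference points `RP_x^L, RP_x^R, RP_y^T,
  RP_y^B, RP_z^T, RP_z^B`; per-axis extents `Dis_a` and slice thicknesses
  `T_a = Dis_a / Num_a`; map a tracked point `Ep` to slice indices via
  `floor((Ep_a − RP_a) / T_a) + 1`.
* **Target picking** — convert a 2D pick `(X_2D, Y_2D)` on slice
  `N_target` to head space,
  `(X_2D·I_X3D/I_dicomX2D, (I_Y3D/N_total)(N_target−1),
  Y_2D·I_Z3D/I_dicomY2D)`, and back.
* **Segmentation** — a U-Net (widths 32/64/128/256/320, 3x3 convolutions
  with batch norm + ReLU, sigmoid output) trained with per-map dice loss,
  Adam at lr 0.003, batch 20, 30 epochs, with grouped 5-fold
  cross-validation at the patient level. Implemented in compiled code
  in-package; gradients are finite-difference-verified in the tests.
* **Recommendation** — 26-connected components of the predicted mask
  volume, largest region, centre voxel, predicted axis plane.
* **Guidance** — trajectory from entry to target, angular deviation of
  the scalpel shaft, remaining depth, and red/yellow/green feedback.
* **Evaluation** — pixel-wise sensitivity/specificity/accuracy, scanning
  plane and target-point errors, tracked-stream stability, boxplot
  summaries with Tukey outliers.

## Worked example

```r
library(evdnav)

# generate a synthetic patient: head phantom with a known ventricle
ph <- generate_head_phantom(phantom_spec(seed = 42))
ph$volume
#> <voxel_volume> 64 x 48 x 64 voxels, spacing 1/1.5/1 mm, origin (0, 0, 0)

# scan the virtual head for its six reference points and slice geometry
head_vol <- crop_volume(ph$volume, mask = ph$truth$head_mask)
occ <- voxel_occupancy(ph$truth$head_mask, spacing = ph$volume$spacing)
frame <- derive_extents(scan_reference_points(occ), head_vol)
frame
#> <reference_frame>
#>   x: [3.500, 60.500] mm  Dis 57.000  T 0.9828  Num 58
#>   y: [3.750, 68.250] mm  Dis 64.500  T 1.4659  Num 44
#>   z: [3.500, 60.500] mm  Dis 57.000  T 0.9828  Num 58

# recommend the surgical target from the ventricle mask
target <- recommend_target(voxel_volume(ph$truth$ventricle_mask,
                                        ph$volume$spacing))
target
#> <recommended_target> voxel (36, 26, 35), plane 26, component 1 (2232 voxels)
#>   head space: (35.50, 38.25, 34.50) mm

# guidance for an insertion from 40 mm above the target
traj <- build_trajectory(entry = target$mm + c(0, 0, 40), target$mm)
tip <- target$mm + c(0, 0, 12)          # 12 mm above the target, on axis
c(deviation_deg = angle_deviation(tip - traj$entry, traj),
  depth_mm = remaining_depth(tip, traj))
#> deviation_deg      depth_mm
#>             0            12
guidance_color(angle_deviation(tip - traj$entry, traj))
#> [1] "green"

# how close is the recommendation to the generator's ground truth?
target_point_error(target$mm, ph$truth$centroid_mm)
#> [1] 0.7633699
```

The reference frame says the scanned head spans 57.0 x 64.5 x 57.0 mm,
giving slice thicknesses of about 0.98/1.47/0.98 mm on the 58/44/58-slice
axes. The recommended target sits on stacking-axis slice 26 at
(35.5, 38.25, 34.5) mm in head space, 0.76 mm from the generator's true
ventricle centroid — within one voxel. An on-axis scalpel tip shows zero
angular deviation (green) with 12 mm of insertion depth remaining.

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "evdnav.R", package = "evdnav"))')" \
    genphantom --seed 7 --out out/
```

with subcommands `genphantom`, `scan`, `train`, `predict`, `recommend`,
`navigate`, `evaluate` and `evaluate-stability`.

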
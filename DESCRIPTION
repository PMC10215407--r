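Package: evdnav
Title: Computational Core of an Image-Guided Navigation Pipeline for
    Extra-Ventricular Drainage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the computational core of an augmented-reality
    navigation workflow for extra-ventricular drainage (EVD) neurosurgery:
    reading and writing single-frame CT DICOM series into a voxel-volume
    model, automatic plane-sweep scanning of a virtual head object to
    establish six axis reference points and per-axis slice thicknesses,
    mapping between tracked 3D positions and DICOM slice indices, a U-Net
    ventricle segmentation network trained with dice loss and grouped
    cross-validation, largest-connected-component surgical target
    recommendation, trajectory generation with color-coded entry-angle
    guidance, and the associated error and stability statistics. Synthetic
    head phantoms with known ground truth make the whole pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
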
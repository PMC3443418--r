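Package: cacscore
Title: Thresholded and Spatially Weighted Coronary Artery Calcium Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies coronary artery calcium (CAC) in non-contrast cardiac
    CT volumes by two methods: the classic thresholded Agatston score
    (connected supra-threshold lesions scored by volume times an
    attenuation-dependent coefficient) and a threshold-free spatially
    weighted calcium score (SWCS) built from calibration-phantom-derived
    per-voxel weights adjusted by neighbourhood attenuation. Includes
    readers and writers for NIfTI volumes, artery-centerline trajectories
    and phantom specifications, a synthetic cardiac-CT cohort generator
    with known ground truth, and test-retest reproducibility statistics
    (percent difference, intraclass correlation, bootstrap comparison of
    scoring methods).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'io.R'
    'roi.R'
    'calibration.R'
    'scoring.R'
    'synthetic.R'
    'repro.R'
    'pipeline.R'
    'cacscore-package.R'
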
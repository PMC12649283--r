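Package: rtdeface
Title: Automated Defacing of Head-and-Neck Radiotherapy CT and DICOM-RT Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes identifiable facial anatomy from head-and-neck
    CT-simulation scans while preserving planning target volumes (PTVs) and
    the brain, and propagates the same defacing to the DICOM-RT Structure
    Set and Dose objects. Uses contoured eyes as landmarks: all voxels on or
    above the inferior-most eye slice and anterior to the eye midpoint are
    removed unless they belong to a PTV or the brain. Includes a minimal
    DICOM reader/writer (Explicit VR Little Endian), contour rasterization
    and mask polygonization, dose-grid resampling, a synthetic head phantom
    generator for validation without patient data, and evaluation metrics
    (Dice overlap, PTV-location classification, Youden-index threshold
    selection on face-embedding distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
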
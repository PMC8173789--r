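Package: socgrade
Title: Subjective-Objective-Combined Grading of Organ-at-Risk Auto-Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for grading the accuracy of auto-segmented radiotherapy
    organs at risk against manual reference contours. Computes five geometric
    contour-comparison indexes on 3D voxel masks (Dice similarity coefficient,
    centre-of-mass distance, relative volume difference, maximum and average
    Hausdorff surface distance), grades them under configurable threshold
    schemes, grades contours subjectively from counts of CT slices requiring
    manual modification, and derives an organ-specific
    subjective-objective-combined (SOC) grading standard from a cohort of
    per-case index values and subjective levels. Includes synthetic phantom
    generators with closed-form expected metrics for validation, NIfTI mask
    input, CSV/JSON interchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
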
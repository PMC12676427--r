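Package: calcrefine
Title: Inpainting-Based Refinement of Microcalcification Detection in
    Mammography-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pixel-level microcalcification detection in 2D
    grayscale mammography-like images. A high-sensitivity candidate mask
    (Stage 1) is refined by inpainting the masked pixels with virtual
    calcification-free values and thresholding the original-minus-virtual
    difference map, removing false positives while preserving true bright
    deposits. Includes multi-scale Gaussian-blur-difference and top-hat
    detectors, a random-mask baseline generative comparator, overlapping
    patch stitching for full-field images, a seeded synthetic phantom
    cohort generator with pixel-exact ground truth, and the full
    pixel-level and patient-level evaluation protocol (sensitivity, PPV,
    Dice, activation rate, conditional detection error, virtual-normal
    fidelity).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    methods,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
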
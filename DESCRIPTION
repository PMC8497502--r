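Package: pixflux
Title: Brightfield Cell-Pixel Quantification and Normalization of Extracellular Flux Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to normalize extracellular flux (Seahorse-style OCR/ECAR)
    measurements of primary cells by the number of cells actually present in
    each well. Implements a brightfield image quantification algorithm
    (Gaussian background estimation, subtraction and inversion, margin
    cropping, thresholded "cell-pixel" counting), a quadratic calibration
    from cell-pixels to seeded cell number, extraction of mitochondrial and
    glycolytic flux metrics (basal, ATP-linked, proton leak, maximal, spare
    respiratory capacity, non-mitochondrial and 2-DG-sensitive rates) from
    injection-phased plate time-courses with a detection-limit QC filter,
    per-cell normalization with within-subject standard scores and
    between-subject coefficients of variation, and synthetic image and
    flux-trace generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
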
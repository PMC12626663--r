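Package: spectracell
Title: Multispectral Autofluorescence Analysis of Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for label-free classification of cells from multispectral
    autofluorescence microscopy. Covers a synthetic multispectral image
    generator with known ground truth (fluorophore spectra, Poisson shot noise,
    sensor defects, uneven illumination), reference-fluid intensity calibration
    (background subtraction, flat-field correction, alignment to
    spectrofluorometer reference values), per-cell spectral feature extraction
    (channel means, SDs, skewness, intensity ratios), entropy-based feature
    selection, and cross-validated binary classification with ROC/AUC
    summaries. Developed around urinary exfoliated proximal tubule cells for
    discriminating causes of kidney transplant dysfunction.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    tiff,
    tools,
    utils
Encoding: UTF-8
Suggests:
    e1071,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
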
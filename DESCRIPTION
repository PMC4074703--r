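Package: dmvq
Title: Quantification of Deep Medullary Vein Visibility and White Matter
    Hyperintensity Burden on SWI/FLAIR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the visibility of deep medullary veins
    (DMVs) on susceptibility-weighted phase images and relating it to white
    matter hyperintensity (WMH) burden on FLAIR MRI. Implements homodyne
    high-pass phase filtering, fitted-Gaussian intensity thresholding for
    WMH (mean + 3 SD) and DMV (mean - 2 SD) segmentation, intracranial-volume
    corrected volumetry, periventricular/deep WMH partitioning by anisotropic
    Euclidean distance, periventricular slab selection, rigid intensity-based
    coregistration, and the cohort statistics layer (partial Pearson
    correlation by residualization, Fisher's exact test by enumeration,
    backward stepwise logistic regression with forced covariates, two-way
    intraclass correlation coefficients, Bonferroni adjustment). Includes a
    seeded synthetic phantom and cohort generator with known ground truth so
    the whole chain is testable without patient data. Reads and writes
    NIfTI-1 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
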
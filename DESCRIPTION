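Package: radstab
Title: Robustness of Radiomic Features to Lung Nodule Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how sensitive quantitative imaging (radiomic)
    features of lung nodules are to the underlying segmentation. Provides a
    synthetic CT nodule cohort generator that emulates a repeated-segmentation
    study design (multiple segmentation algorithms, each run with multiple
    initializations), a reference implementation of a radiomic feature set
    spanning size, global and local shape, intensity, margin, and texture
    (gray-level co-occurrence, run-length, Law's energy, Laplacian-of-Gaussian,
    and wavelet) features, repeated-measures concordance correlation analysis
    of per-feature stability to segmentation, and correlation-graph analysis
    of feature redundancy via thresholded connected subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
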
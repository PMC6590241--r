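Package: msiqc
Title: Quality Control Metrics for MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control computations for MALDI mass spectrometry
    imaging (MSI) of formalin-fixed paraffin-embedded tissue sections:
    a mixed-pixel spatial-resolution score based on the overlap of two
    region-specific ion images, spectral-quality metrics (peak counts
    with percentile-bootstrap confidence intervals of the median),
    cross-run peak-intensity coefficient-of-variation tables, and
    spatial segmentation by bisecting k-means with correlation distance
    plus principal-component analysis with unit-variance scaling.
    Includes imzML 1.1 input/output (continuous and processed modes),
    TIC normalization, ion-image extraction, tissue-mask handling,
    MAD-based noise estimation with monoisotopic (averagine-envelope)
    peak picking, and a synthetic two-region MSI phantom generator with
    ground truth, controllable analyte delocalization and condensation
    droplet artifacts, so that every scoring operation is testable
    against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    xml2,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
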
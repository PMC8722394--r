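Package: smfishloc
Title: Quantification of Subcellular mRNA Localization from smFISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying subcellular mRNA
    localization in epithelial cells from single-molecule FISH (smFISH)
    microscopy: Laplacian-of-Gaussian spot detection with subpixel Gaussian
    fitting, intensity-unit calibration from the dimmest spots to convert
    spot amplitudes into mRNA counts, polygon-ROI compartment assignment
    (total / interior / nuclear / apical outlines) with membrane counts
    obtained by subtraction, apicobasal intensity-profile analysis with
    nuclear-signal eviction and junction peak calling on an apical-junction
    marker channel, and per-condition box-plot summaries with Welch t-tests.
    Includes a ground-truthed synthetic-embryo image simulator emulating
    seam-cell epithelia (polygonal cell rows, junction belts, nuclei,
    diffraction-limited spots with per-spot mRNA multiplicity, Gaussian PSF,
    Poisson plus Gaussian noise) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    pracma,
    minpack.lm,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
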
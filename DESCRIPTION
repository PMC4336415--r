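Package: dropMetrics
Title: Droplet Volume Metrology and Copy-Number Quantification for
    Droplet Digital PCR
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for metrological droplet digital PCR (ddPCR): sizing of
    emulsion droplets from brightfield micrographs (edge-based segmentation,
    watershed separation of touching droplets, elliptical fit, area-equivalent
    and Feret diameters, sphere-equivalent volumes), conversion of partition
    counts to copy-number concentrations with Poisson partition statistics and
    gravimetric dilution corrections, intermediate-precision uncertainty from
    one-way random-effects ANOVA across measurement days, and bias assessment
    of measured concentrations against certified reference material values
    using combined expanded uncertainties (k = 2). Includes a synthetic-data
    module that renders droplet-monolayer images with known ground truth and
    simulates partition counts, fluorescence amplitudes and gravimetric
    dilution records, so every step of the pipeline can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: Software, CellBiology, QualityControl, DNASeq
Config/testthat/edition: 3
RoxygenNote: 7.3.3
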
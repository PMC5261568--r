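Package: ftirmark
Title: FTIR Microspectroscopy Workflow for Detecting Skin Electrical Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested chemometrics pipeline for discriminating skin
    electrical marks from normal skin by mid-infrared microspectroscopy.
    Provides a synthetic-spectrum generator with class-specific Amide I
    band compositions and scatter distortions, extended multiplicative
    signal correction (EMSC), Savitzky-Golay second-derivative
    preprocessing, protein secondary-structure band detection and
    assignment, PCA exploration with confidence ellipses, dummy-coded
    PLS1 classification with leave-one-out cross-validation and Y-value
    thresholds, and pixel-wise classification of hyperspectral tissue
    maps into pseudo-colored digital images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    signal,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synthgen.R'
    'preprocess.R'
    'bandanalysis.R'
    'chemometrics.R'
    'mapclassify.R'
    'io.R'
    'pipeline.R'
    'ftirmark-package.R'
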
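Package: lctrs
Title: HPLC Retention Time Prediction by Linear Calibration with Two
    Reference Substances
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts HPLC retention times of compounds lacking reference
    substances from a panel of multi-column retention data.  Implements the
    LCTRS workflow (two-point linear calibration against standard retention
    times, window-based peak matching with a sequential rule, and
    multiple-point regression validation), the competing relative-retention
    (RR) method for benchmarking, panel quality control (outlier column and
    compound exclusion, reference-pair selection, column-subsampling study),
    and a seeded synthetic panel generator.  Retention panels are stored as
    SummarizedExperiment-derived objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Metabolomics, Proteomics, MassSpectrometry, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
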
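Package: fuseMS
Title: Mid-Level Fusion of Dual-Platform Mass-Spectrometry Fingerprints for
    Food-Origin Authentication
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Chemometric workflow for authenticating the geographical origin
    and production method of food products from two mass-spectrometry blocks:
    ambient lipid fingerprints (binned high-resolution spectra) and ICP-MS
    element concentration profiles. Implements spectral peak-list parsing
    (lockmass correction, background subtraction, TIC thresholding, 0.2 Da
    binning), element-panel normalisation and filtering, low- and mid-level
    data fusion with PCA block compression, NIPALS PCA/PLS-DA/OPLS-DA with
    S-plot and VIP marker selection, cross-validated classification with
    Hotelling T2 / distance-to-model outlier screening, nonparametric
    element statistics, a monoisotopic mass calculator with a curated salmon
    lipid marker panel, and a synthetic two-block data generator that
    emulates a five-group salmon cohort for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Classification, Software
RoxygenNote: 7.3.3
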
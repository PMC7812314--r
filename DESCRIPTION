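Package: maldiMLP
Title: Protein Identification in MALDI Imaging Mass Spectrometry by
    Maximum-Likelihood Matching to Shotgun Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the most likely parent proteins of peptide masses
    measured by MALDI imaging mass spectrometry (IMS). Per-pixel centroided
    spectra are binned onto a common m/z axis and segmented by unbiased
    hierarchical clustering; cluster-wise peak lists are deisotoped using
    averagine isotope spacing, intensity-ratio tolerances and spatial
    co-localization; deisotoped monoisotopic masses are matched within a
    mass tolerance to an LC-MS/MS peptide evidence table scored by an
    empirical-Bayes moderated t-test, and each IMS mass is assigned to the
    candidate peptide maximizing the MLP score (mean intensity times
    absolute log2 fold change over moderated p-value). Includes
    missing-not-at-random imputation, protein presence and enrichment
    filters, hypergeometric over-representation analysis, a ground-truthed
    synthetic-data generator, imzML and tabular I/O, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Matrix,
    xml2,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
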
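Package: apmstools
Title: Differential Interactome Analysis for AP-MS with RNAi Screen and
    PLA Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for affinity-purification mass-spectrometry
    (AP-MS) differential enrichment analysis on label-free iBAQ
    quantification tables in the MaxQuant proteinGroups dialect: artifact
    row exclusion, log2 transformation, sample-median normalization,
    minimum-valid-value filtering, per-replicate imputation from a
    down-shifted normal distribution, and an S0-moderated two-sided Welch
    test with permutation-based false-discovery-rate control. Downstream
    tools derive bait interactor sets and their overlap decomposition,
    call hits in shRNA reporter screens by a dual-shRNA dual-stimulus
    reduction rule, and compute proximity-ligation-assay (PLA) scores from
    confocal z-stacks by thresholded, size-filtered particle counting per
    cell. Synthetic-data generators with known ground truth exercise every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
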
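Package: kaspHI
Title: Hybrid-Index Estimation from KASP End-Point Fluorescence in eDNA and
    Swab Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequencing-free screening of hybrid populations from
    Kompetitive Allele-Specific PCR (KASP) end-point fluorescence. Maps raw
    FAM/HEX intensities from skin-swab and environmental DNA (eDNA) samples
    to a hybrid index via per-SNP centroid-angle calibration, with quality
    control (read-cycle selection against no-template controls,
    low-fluorescence filtering, replicate averaging, genotype-mismatch
    flagging, robust median+MAD outlier exclusion), population-level
    ancestry aggregation, and the full validation-statistics battery
    (SNP-bias bootstrap screening, Spearman concordance, permutation ANCOVA,
    Kruskal-Wallis and Wilcoxon profile tests, Fligner-Killeen variance
    comparisons, Bland-Altman agreement, biomass-corrected expectations).
    Includes a synthetic fluorescence-data simulator reproducing the
    mesocosm study design for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
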
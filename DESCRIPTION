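Package: sulfostress
Title: Growth, Lipid, Transcript and Protein Stress-Response Analysis for
    Saccharolobus islandicus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for batch-culture stress experiments with the
    thermoacidophilic archaeon Saccharolobus islandicus: doubling-time and
    maximum-density estimation from OD600 growth curves, GDGT (glycerol
    dibiphytanyl glycerol tetraether) lipid composition and ring-index
    profiling, differential gene expression calling with directional Venn
    accounting across stresses, a layered-uncertainty Z-score procedure for
    differential protein abundance with Benjamini-Hochberg correction, and
    transcript-protein concordance classification. Includes a seeded
    multi-omics synthetic data generator that emulates the three-condition
    (optimal, acid, cold) by two-phase (mid-log, early stationary) triplicate
    design, with a ground-truth manifest for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
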
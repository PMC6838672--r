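Package: tloopr
Title: Kinome-Wide T-Loop Phosphorylation SRM Assay Design and
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Design and quantification toolkit for targeted mass
    spectrometry (SRM/MRM) assays monitoring kinase activation-loop
    (T-loop) phosphorylation. Locates DFG..APE activation segments in
    kinase sequences, digests in silico and emits target phosphopeptide
    lists, builds and schedules light/heavy transition sets in survey and
    quantification modes, integrates chromatographic peaks with
    rdotp-based acceptance and on/off noise substitution, derives
    limits of detection and quantification from dilution-series
    regressions, resolves shared peptides into kinase groups, and tests
    condition differences on analyte/internal-standard ratios. Includes
    seed-deterministic generators for synthetic kinomes, chromatograms
    and dilution series with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
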
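Package: massmapr
Title: In-Silico Primary-Structure Characterization of Glycosylated
    Fc-Fusion Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the mass-spectrometry-based primary-structure
    characterization of therapeutic fusion proteins such as VEGF-trap
    receptor decoys. Implements simulated protease digestion with
    coordinate-annotated peptides, modification-aware monoisotopic and
    average peptide mass prediction, tolerance matching of observed peak
    lists with sequence-coverage reporting, N-glycosylation sequon
    detection and PNGase F occupancy assessment, exhaustive enumeration
    of disulfide-linked di-peptides with scrambling checks, glycan
    composition arithmetic including 2-AA labeling and per-site
    glycoform assignment, and a Henderson-Hasselbalch isoelectric-point
    model that explains the acidic shift observed by capillary
    electrophoresis upon deglycosylation. A seeded synthetic-data module
    generates homodimeric two-chain fixtures and noisy peak lists so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
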
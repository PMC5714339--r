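Package: footcall
Title: Automated DNase I Footprint Calling from Capillary Electrophoresis Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An automated DNase I footprinting pipeline for fragment-analysis
    (capillary electrophoresis) data. Starting from Peak Scanner-style peak
    tables, footcall normalizes peak heights against the internal size
    standard, aggregates replicates into per-residue cleavage profiles,
    computes BSA/transcription-factor protection ratios, and calls footprints
    from clustered protected residues with strand reconciliation. Downstream
    modules scan IUPAC degenerate binding motifs (DBE, FKH) on both strands,
    compute per-fragment motif densities, derive degenerate consensus
    sequences from detected sites, and project footprints across species
    through a supplied multiple alignment, including inverted alignment
    segments. A seeded simulator generates synthetic peak tables with planted
    footprints so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
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
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
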
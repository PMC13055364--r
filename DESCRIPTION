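Package: paleodens
Title: Mining and Codivergence Dating of Endogenous Densovirus NS1 Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering endogenous densovirus NS1 "molecular
    fossils" in host genome assemblies and analysing their evolutionary
    history. Provides a six-frame translated homology search against an NS1
    reference panel, ORF mining under alternative (flatworm mitochondrial)
    genetic codes, pairwise identity matrices with ICTV Parvoviridae species
    and genus demarcation, flanking-sequence GC analysis as integration
    evidence, relative-rate (RelTime-style) divergence dating with host
    calibrations, sliding-window recombination detection (MaxChi, Chimaera
    and a BootScan-like track) with permutation significance, and Kabsch
    superposition of NS1 structural domains. A synthetic-data generator with
    known ground truth makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
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
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
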
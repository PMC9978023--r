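Package: stempcr
Title: In Silico Design and Mechanism Simulation for Specific Terminal
    Mediated PCR (STEM-PCR)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and simulate Specific Terminal Mediated PCR
    (STEM-PCR) assays entirely in silico. STEM-PCR gates exponential
    amplification on a template strand carrying a sequence-specific
    terminus, produced by methylation-dependent restriction enzyme (MDRE)
    digestion, by a PNA polymerase block at a point mutation, or by paired
    cuts for co-methylation analysis of fragmented cell-free DNA. The
    package provides an oligonucleotide designer (foldable primers, cut
    helpers, bridge primers, artificial primers and probes) driven by
    nearest-neighbor DNA thermodynamics, per-molecule reaction pathway
    simulation from digestion through hairpin self-priming to a predicted
    Ct, methylation-aware in silico digestion with the GlaI, MspJI, FspEI
    and LpnPI enzyme models, and seeded synthetic-template and
    fragment-pool generators for fully reproducible desk-scale studies.
License: MIT + file LICENSE
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
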
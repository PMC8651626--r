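Package: aeropollen
Title: Molecular Airborne Pollen Monitoring by DNA Metabarcoding
Version: 0.1.0
Authors@R:
    person("Aeropollen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, self-contained re-implementation of a molecular
    airborne-pollen monitoring analysis: amplicon read merging, primer
    trimming, dereplication and unoise-style denoising into zero-radius
    OTUs; dual-database taxonomic assignment with tied-score lowest common
    ancestor and identity-tier rank capping; a six-step contamination
    filter cascade with a data-driven tag-jump leakage threshold;
    semi-quantitative comparison of relative read abundances against
    microscopic pollen concentrations; and Bray-Curtis / perMANOVA / NMDS
    site-season community comparison. A synthetic aerobiological data
    generator (hierarchically diverged reference databases, marker-specific
    amplification bias, PCR-replicate overdispersion, read errors, leakage
    into blanks, food contaminants, multinomial microscope counts) drives
    the whole pipeline so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
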
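Package: circsponge
Title: CircRNA Discovery, Characterization, and Sponge-Network Construction
Version: 0.1.0
Authors@R:
    person("circsponge", "developers", email = "circsponge@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, self-contained pipeline for circular RNA
    (circRNA) analysis from RNA-seq reads: anchor-based back-splice
    junction (BSJ) detection with canonical GT-AG splice-signal
    filtering, junction-read counting and per-million normalization,
    circRNA signature statistics (BSJ-read categories, chromosome
    density, length distribution), circRNA-miRNA-mRNA sponge-network
    construction from seed-site matches and nearest-neighbor RNA duplex
    energies, divergent/convergent validation-primer template design,
    and dual-luciferase interaction statistics. A synthetic-data module
    generates genomes, planted circular/linear transcripts, reads,
    miRNAs, and luciferase plates so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    igraph,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
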
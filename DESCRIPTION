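Package: taxoprofile
Title: Taxonomic Visualisation of Protein Presence from Homology Searches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for phylogenetic profiling of protein presence-absence
    from protein homology searches. Parses BLASTp results in XML2 format,
    applies user-set e-value and minimum-length cutoffs with cross-hit
    checks between query proteins, combines filtered hits per protein, and
    visualises presence either as NCBI-taxonomy trees carrying
    combination-coded, count-scaled pie charts per node, or as an
    interactive clustered heatmap of capped -log10(e-value) significance
    scores. Includes a workspace-based command-line front end, quality
    check plots (hit length histogram, six-interval coverage profile),
    FASTA extraction of hit sequences, and a deterministic synthetic-data
    generator producing miniature taxonomy dumps and BLAST XML2 documents
    for testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
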
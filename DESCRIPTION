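Package: nirkit
Title: Classification and Comparative Genomics of Copper Nitrite Reductase (NirK)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the classification of copper-containing nitrite
    reductase (NirK) protein sequences into the two major phylogenetic
    clades, based on conserved copper-ligand and active-site residues,
    clade-diagnostic seven-residue deletions, active-site sequence motifs
    and N-/C-terminal domain extensions, all expressed in a common
    reference residue numbering. Includes neighbour-joining phylogenetics
    with bootstrap support, in-silico evaluation of degenerate nirK PCR
    primers (mismatch profiles, binding-region sequence logos, amplicon
    prediction), classification of genome gene inventories into
    denitrification and DNRA (dissimilatory nitrate reduction to ammonium)
    pathway categories with hypergeometric co-occurrence statistics, and a
    fully seeded synthetic-data generator that emulates the statistical
    structure of curated NirK datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
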
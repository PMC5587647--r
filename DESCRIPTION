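Package: repeatscope
Title: Repeat-Level Comparative Analysis of WD40 Beta-Propeller Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for repeat-level analysis of WD40 beta-propeller proteins:
    an internal-sequence-identity statistic with Highly-Repetitive (HR) and
    Moderately-Repetitive (MR) classification, DH[S/T]W tetrad calling and
    tetrad density on a canonical blade template, proteome abundance
    statistics with rank-sum tests and fold changes, prokaryotic
    gene-neighbourhood (operon-proxy) clustering with bidirectional-best-hit
    conservation analysis, and Nei-Gojobori (NG86) dN/dS estimation between
    repeat pairs under standard or bacterial genetic codes. Includes a
    synthetic-data module that simulates WD40 genes by repeat duplication
    followed by codon divergence, proteome collections with set abundances,
    and genomes with planted gene clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
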
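Package: plastokit
Title: Comparative Structural and Diversity Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of complete chloroplast genomes
    (plastomes): detection of the quadripartite LSC/IRb/SSC/IRa structure and
    classification of inverted-repeat junction types, MISA-style microsatellite
    (SSR) scanning plus tandem and dispersed/palindromic repeat detection,
    per-region nucleotide diversity, selection of highly variable regions as
    candidate DNA barcodes with neighbor-joining/bootstrap discrimination
    scoring, region-size correlation analysis, and a pairwise NG86 Ka/Ks
    screen. Includes a synthetic plastome-family generator with known ground
    truth (structure, repeats, substitution-rate hotspots, tree) so every
    stage has a recovery test without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
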
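Package: coasm
Title: Colored de Bruijn Graph Coassembly of Single-Cell Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coassembly of multiple single-cell read data sets on a single
    colored de Bruijn graph. Each data set ("color") contributes per-k-mer
    multiplicities to a shared vertex set; contigs are extracted in a
    color-oblivious manner so that regions lost to multiple displacement
    amplification (MDA) dropout in one cell are rescued by coverage in
    another. Includes progressive coverage-cutoff trimming with multi-color
    rescue, tip clipping, pairwise shared/exclusive sequence decomposition
    and the exclusivity-ratio matrix, assembly length statistics (N50/NG50),
    a k-mer based reference evaluator, an MDA-bias read simulator with
    blackout regions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    optparse,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
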
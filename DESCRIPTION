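Package: kdrhaplo
Title: Pooled Amplicon Haplotype Calling and kdr Origin Inference for
    Aedes aegypti Sodium-Channel Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying knockdown-resistance (kdr) alleles of the
    voltage-gated sodium channel in Aedes aegypti from pooled, barcoded
    amplicon sequencing of the IIS6 and IIIS6 segments.  Provides a
    synthetic reference panel and pooled-read simulator with an
    Ion-Torrent-like error model, demultiplexing and abundance-based
    denoising into per-population haplotype frequency tables, codon-aware
    annotation of amino-acid changes under housefly (Musca domestica)
    residue numbering, statistical-parsimony haplotype networks, an
    intron-based clade bipartition of IIS6 haplotypes, cross-segment
    phasing in populations monomorphic for one segment, inference of the
    minimum number of independent origins of a kdr mutation, and temporal
    frequency-trajectory summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
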
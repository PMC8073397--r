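Package: MitoCMS
Title: Candidate Gene Screening for Cytoplasmic Male Sterility in Plant
    Mitochondrial Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying candidate cytoplasmic male sterility
    (CMS) genes in assembled plant mitochondrial genomes. Implements
    six-frame open reading frame (ORF) scanning on circular genomes,
    seed-and-extend local nucleotide alignment with Karlin-Altschul
    E-values, mitotype-specific sequence (MSS) detection against a genome
    panel with presence/absence matrices, UPGMA clustering of mitotypes
    under the Cavalli-Sforza-Edwards chord distance, maximal exact repeat
    discovery, hydropathy-based transmembrane segment calling, chimeric
    protein decomposition with domain lift-over, and delta SNP-index
    bulked-segregant statistics with simulation-based confidence bands
    for restorer-of-fertility QTL mapping. A synthetic-data module
    generates genome panels, fusion proteins and bulk allele-count tables
    with planted truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
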
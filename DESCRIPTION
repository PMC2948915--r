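Package: ublcontext
Title: Comparative Genomic Context Analysis of Ubiquitin-Like Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering small ubiquitin-like (Ubl) protein families
    in prokaryotic genomes and inferring their functional partners by guilt by
    association. Implements consensus-based scanning of ortholog-cluster
    alignments for conserved C-terminal GG/CC doublets, extraction and
    cross-genome scoring of gene neighborhoods, operon and divergent-gene
    prediction, domain-fusion detection, phyletic (presence/absence) pattern
    queries, and protein maximum-likelihood phylogenetics under the JTT model
    with neighbor-joining starting trees, nearest-neighbor-interchange search
    and RELL bootstrap supports. A synthetic-data module generates genomes,
    cluster families and alignments with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
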
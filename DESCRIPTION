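Package: melacog
Title: Ortholog Clustering, Taxonomic Voting and Genome Assessment for
    Small Sets of Reconstructed Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for comparative analysis of a small set of
    reconstructed (metagenome-assembled) genomes: a bundled Smith-Waterman
    protein aligner with Karlin-Altschul e-value scaling, reciprocal-best-hit
    ortholog clustering into one-member-per-genome clusters (COGs) under a
    degree-based connectivity rule, best-hit majority-vote phylum assignment
    using the identical-positions margin rule, KEGG Orthology pathway-category
    assignment, single-copy-marker completeness grading with assembly
    statistics (N50, GC), RNase P RNA (RnpB) motif scanning, flagellin TLR5
    region extraction, and 16S rRNA survey abundance tallying. A seeded
    synthetic-data generator with planted ground truth exercises every stage
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
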
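Package: kmercosine
Title: Alignment-Free Metagenome Comparison via Canonical k-mer Cosine Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares whole-metagenome samples from their assembled contigs
    without alignment. Each sample is reduced to a sparse frequency vector of
    canonical k-mers (each k-mer pooled with its reverse complement, so
    profiles are strand-invariant), pairwise cosine distances are computed on
    the full vectors, and the resulting distance matrix feeds neighbour-joining
    trees, principal coordinates analysis, and rank-sum comparisons of
    within- and between-group distances. Includes a seeded simulator of
    grouped contig samples for end-to-end validation, readers and writers for
    FASTA, PHYLIP and TSV distance matrices and Newick trees, and a
    subcommand-style command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    optparse,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
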
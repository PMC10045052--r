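Package: pasdist
Title: Reference-Free Genome Distances from Reads and Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates pairwise Levenshtein distances between genomes
    directly from sequencing reads and partially assembled contigs,
    without a reference genome and without completing the assembly.  Reads
    and contigs of two samples are matched four ways (read-read,
    read-contig, contig-reads, contig-contig) using a margin-tolerant edit
    distance, redundancy filtering and weighted interval scheduling, and
    the four facets are combined into a single estimate of the number of
    point mutations separating the genomes.  A q-gram (k-mer) profile
    filter with sliding-window updates accelerates all matching steps.
    Includes neighbor-joining tree construction, tree and matrix
    comparison metrics (Pearson correlation, Fowlkes-Mallows index,
    triplet distance), and a simulator producing reads, contigs and
    ground-truth distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
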
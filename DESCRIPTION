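Package: txcombine
Title: Merge Independent De Novo Transcriptome Assemblies into a
    Non-Redundant Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines many small per-library de novo transcriptome
    assemblies into one large, low-redundancy transcriptome. Predicted
    transcripts from all libraries are indexed in a compacted bidirected
    de Bruijn graph; each transcript is threaded through the graph,
    unambiguously extended at both ends within its terminal unitigs, and
    filtered by the average node length of its path. Transcripts are then
    ranked by path node count and a greedy pass retains only transcripts
    that contribute an uncovered long node, after which survivors are
    grouped into loci by transitively shared long nodes. Includes FASTA/
    FASTQ readers, a Phred quality read trimmer, a synthetic fixture
    generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    stringi,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
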
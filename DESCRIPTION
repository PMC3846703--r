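Package: quasialignr
Title: Alignment-Free Discovery of Conserved Regions via Quasi-Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers regions of high similarity across multiple unaligned
    DNA sequences without multiple sequence alignment. Sequences are cut into
    fixed-length segments, each segment is summarized by its p-mer count
    vector (a Numerical Summarization Vector, NSV), and the stream of NSVs is
    clustered in a single pass with a threshold nearest-neighbour rule. The
    resulting clusters ("quasi-alignments") together with a directed
    transition graph form a GenModel, from which per-position consensus
    profiles and conserved regions are derived. Includes a synthetic sequence
    family generator with planted conserved windows, graph and track
    visualizations, and exports to FASTA, TSV, BED, JSON, DOT and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    ggplot2,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
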
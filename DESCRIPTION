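Package: readbloom
Title: Reference-Free Compression of Sequencing Reads with a
    Probabilistic de Bruijn Graph
Version: 0.1.0
Authors@R:
    person("readbloom", "developers", email = "readbloom@example.org",
           role = c("aut", "cre"))
Description: Compresses FASTQ and FASTA short-read files without a
    reference genome.  Solid (abundant) kmers of the read set are stored
    in a Bloom filter that acts as a probabilistic de Bruijn graph; each
    read is then recorded as an anchoring kmer plus the list of
    bifurcation choices needed to retrace its path through the graph.
    Component streams (read lengths, anchor indices, bifurcation events,
    headers) are entropy-coded with an adaptive order-0 range coder,
    and quality scores are either kept lossless or smoothed using
    solid-kmer coverage evidence before DEFLATE compression.  Headers
    and sequences always round-trip byte-exactly.  A deterministic read
    simulator with ground-truth error positions supports testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
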
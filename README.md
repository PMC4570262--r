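# readbloom

Reference-free compression of high-throughput sequencing reads
(FASTQ/FASTA), for people who store or move read sets and do not want to
depend on a reference genome being available at decompression time.

## The idea

General-purpose compressors see a FASTQ file as text; the redundancy
that matters — every genomic position sequenced tens of times — is
spread over the whole file where no sliding window can reach it.
`readbloom` first builds that missing reference *de novo* from the reads
themselves, as a de Bruijn graph: the *solid* kmers (canonical kmers of
length *k* whose dataset-wide count reaches an abundance threshold
*T*<sub>sol</sub> inferred from the kmer-count histogram) become graph
nodes, and an edge a→b exists when the (k−1)-suffix of a equals the
(k−1)-prefix of b. The node set is stored in a Bloom filter — about 12
bits per node instead of the 8⌈k/32⌉+1 bytes per node of an exact
hash-table graph — making the graph cheap enough to ship inside the
compressed file. The filter's one-sided errors never lose data; a false
positive merely costs an extra bifurcation symbol.

Each read is then recorded as a path in this graph:

* an **anchor** — a solid kmer of the read, stored once in a shared
  dictionary and referenced by integer index (the analogue of a mapping
  position);
* the **read length** and **anchor offset**;
* two **bifurcation lists** (right and left of the anchor): nothing on
  simple paths, a nucleotide at true graph branchings, and a
  (nucleotide, position) pair where the read departs from the graph —
  typically a sequencing error.

Reads with no solid kmer (≥1 error every *k* bases, or low-covered
regions — rare) are stored verbatim. Headers are tokenized and
delta-coded against the previous header (field match / numeric delta /
shared prefix). Every component stream gets its own adaptive order-0
arithmetic (range) coder. Qualities are DEFLATE-compressed, either
losslessly or (default) after graph-based smoothing: a quality `q` at a
position covered by at least σ solid kmers is replaced by `'@'`, with
σ = 2 if δ ≤ 10 and σ = δ − 5 otherwise, δ = code('@') − code(q) — the
lower the original quality, the more coverage evidence is demanded.
Headers and sequences always round-trip byte-exactly; memory scales with
genome size, not file size.

## Worked example

```r
library(readbloom)
fq <- tempfile(fileext = ".fastq")
rb_simulate(fq, genome_length = 5e5, coverage = 70, read_length = 100,
            substitution_rate = 0.01, seed = 7)   # 350,000 simulated reads
cont <- tempfile(fileext = ".rbf")
s <- rb_compress(fq, cont)                        # defaults: k=31, b=12, lossy
str(s[c("n_reads", "t_sol", "n_anchors", "n_raw_reads",
        "stream_bytes", "ratio")])
```

```
$ n_reads     : int 350000
$ t_sol       : int 5
$ n_anchors   : num 55167
$ n_raw_reads : int 1145
$ stream_bytes: Named num [1:5] 749951 427694 1760929 1509916 2085973
 ..- names: "bloom" "dict" "sequence" "headers" "quality"
$ ratio       : num 12
```

Reading the numbers: the abundance histogram put the solidity threshold
at 5; 350,000 reads share 55,167 dictionary anchors (≈ 6 reads per
anchor); only 1,145 reads (0.3 %) could not be anchored. The 78.6 MB
FASTQ became 6.5 MB — ratio 12.0 (original size / compressed size),
versus 2.2 for `gzip` on the same file — with the graph (0.75 MB) and
dictionary (0.43 MB) amortized over all reads and the sequence stream at
0.42 bits/base. Decompression needs only the container:

```r
out <- tempfile(fileext = ".fastq")
rb_decompress(cont, out)
identical(read_fastx(out)$sequence, read_fastx(fq)$sequence)  # TRUE
```

With `lossless_qual = TRUE` the output file is byte-identical to the
input; in the default lossy mode, headers and sequences are still exact
and only qualities are smoothed.

A command-line front end wraps the same functions:

```sh
Rscript -e 'readbloom::rb_cli()' compress -i in.fastq -o out.rbf
Rscript -e 'readbloom::rb_cli()' decompress -i out.rbf -o back.fastq
Rscript -e 'readbloom::rb_cli()' simulate -o sim.fastq --coverage 70 --seed 1
```

(or `Rscript inst/cli/readbloom.R ...` from a checkout; `--help` on each
subcommand).

## Layout

* `R/`, `src/` — implementation (Rcpp core: kmers, Bloom graph, range
  coder, path codec, header codec, simulator).
* `inst/FORMAT.md` — byte-level container specification.
* `vignettes/readbloom-methods.Rmd` — model, parameters, design choices,
  limitations.
* `tests/testthat/` — unit, property and acceptance tests.
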
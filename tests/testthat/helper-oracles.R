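# Independent pure-R oracles, deliberately kept separate from the package's
# C++ code paths.

oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  ifelse(s <= rc, s, rc) # lexicographic == packed 2-bit order for this code
}

oracle_kmerize <- function(seq, k) {
  l <- nchar(seq)
  if (l < k) return(character(0))
  substring(seq, 1:(l - k + 1L), k:l)
}

# canonical kmer counts as a named integer vector; windows with non-ACGT skipped
oracle_count_kmers <- function(reads, k) {
  km <- unlist(lapply(reads, oracle_kmerize, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(integer(0))
  tab <- table(oracle_canonical(km))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# all canonical kmers of a genome (both-strand identity)
genome_kmers <- function(genome, k) {
  unique(oracle_canonical(oracle_kmerize(genome, k)))
}

# exact toy graph: Bloom filter generously sized to make FPs negligible,
# built from an explicit kmer list
toy_graph <- function(kmers, k = nchar(kmers[1L]), bits = 20L) {
  build_graph(solid_set(kmers, k), bits)
}

# adaptive order-0 log-loss of a symbol stream under the package's stated
# model (counts start 1, +8 per symbol, halved above 2^16), in bits
oracle_logloss <- function(symbols, nsym) {
  counts <- rep(1, nsym)
  total <- nsym
  bits <- 0
  for (s in symbols) {
    bits <- bits - log2(counts[s + 1L] / total)
    counts[s + 1L] <- counts[s + 1L] + 8
    total <- total + 8
    if (total > 65536) {
      counts <- (counts + 1) %/% 2
      total <- sum(counts)
    }
  }
  bits
}

random_dna <- function(n, len, chars = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(chars, len, replace = TRUE), collapse = "")
  }, character(1L))
}

# random FASTQ read set: printable headers, ACGTN sequences of mixed length
# (including reads shorter than k), printable Phred+33 qualities
fuzz_read_set <- function(n_reads, max_len = 120L, n_rate = 0.02) {
  headers <- vapply(seq_len(n_reads), function(i) {
    len <- sample(0:40, 1L)
    if (len == 0L) return("")
    paste(sample(strsplit(rawToChar(as.raw(32:126)), "")[[1L]], len,
                 replace = TRUE), collapse = "")
  }, character(1L))
  seqs <- vapply(seq_len(n_reads), function(i) {
    len <- sample(0:max_len, 1L)
    if (len == 0L) return("")
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(rep((1 - n_rate) / 4, 4), n_rate)), collapse = "")
  }, character(1L))
  quals <- vapply(nchar(seqs), function(l) {
    if (l == 0L) return("")
    paste(sample(strsplit(rawToChar(as.raw(33:74)), "")[[1L]], l,
                 replace = TRUE), collapse = "")
  }, character(1L))
  read_set(headers, seqs, quals)
}
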
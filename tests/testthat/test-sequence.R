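# toy setting: exact linear genome graph, generously sized Bloom filter so
# false positives are negligible; k = 15 keeps canonical collisions (spurious
# strand-overlap branches) out of the toy genome
K <- 15L
GENOME <- generate_genome(400, 161)
GRAPH <- toy_graph(genome_kmers(GENOME, K), K, bits = 24L)

test_that("anchor selection: dictionary hit beats new solid kmer", {
  read <- substr(GENOME, 51, 150)
  dict <- anchor_dict(K)
  # fresh dictionary: leftmost solid kmer appended, index 0 at offset 0
  a <- select_anchor(read, dict, GRAPH)
  expect_equal(a, list(index = 0, position = 0))
  expect_equal(dict_size(dict), 1)
  expect_identical(dict_get(dict, 0), substr(read, 1, K))
  # pre-registered interior kmer wins over the (solid) leftmost kmer
  dict2 <- anchor_dict(K)
  inner <- substr(read, 6, 5 + K)
  readbloom:::.rb_dict_add(dict2$ptr, inner)
  a2 <- select_anchor(read, dict2, GRAPH)
  expect_equal(a2, list(index = 0, position = 5))
  expect_equal(dict_size(dict2), 1) # nothing appended
})

test_that("a read on a simple path needs no bifurcation symbols", {
  read <- substr(GENOME, 51, 150)
  ev <- encode_read(read, 0, GRAPH)
  expect_equal(nrow(as.data.frame(ev$right)), 0)
  expect_equal(nrow(as.data.frame(ev$left)), 0)
  dec <- decode_read(substr(read, 1, K), 0, nchar(read), ev, GRAPH)
  expect_identical(dec, read)
})

test_that("one substitution in a non-branching region costs one positional event", {
  read <- substr(GENOME, 51, 150)
  p <- 61L # 1-based, well right of the anchor
  orig <- substr(read, p, p)
  sub <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(read, p, p) <- sub
  ev <- encode_read(read, 0, GRAPH)
  right <- as.data.frame(ev$right)
  expect_equal(nrow(right), 1)
  expect_equal(right$type, 1L)          # positional ("error") event
  expect_equal(right$nucleotide, sub)
  expect_equal(right$position, p)
  expect_equal(nrow(as.data.frame(ev$left)), 0)
  dec <- decode_read(substr(read, 1, K), 0, nchar(read), ev, GRAPH)
  expect_identical(dec, read)
})

test_that("a substitution left of the anchor is a left-walk positional event", {
  read <- substr(GENOME, 51, 150)
  substr(read, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(read, 4, 4))[1]
  dict <- anchor_dict(K)
  a <- select_anchor(read, dict, GRAPH)
  expect_equal(a$position, 4) # kmers 0..3 all overlap the error
  ev <- encode_read(read, a$position, GRAPH)
  left <- as.data.frame(ev$left)
  expect_equal(nrow(left), 1)
  expect_equal(left$type, 1L)
  expect_equal(left$position, 4)
  dec <- decode_read(dict_get(dict, a$index), a$position, nchar(read), ev, GRAPH)
  expect_identical(dec, read)
})

test_that("crossing a true branch costs one nucleotide-only event", {
  prefix <- substr(GENOME, 1, 60)
  tail1 <- paste0("A", generate_genome(59, 62))
  tail2 <- paste0("C", generate_genome(59, 63))
  v1 <- paste0(prefix, tail1)
  v2 <- paste0(prefix, tail2)
  g <- toy_graph(unique(c(oracle_kmerize(v1, K), oracle_kmerize(v2, K))),
                 K, bits = 20L)
  read <- substr(v1, 41, 100) # spans the junction at offset 60
  ev <- encode_read(read, 0, g)
  right <- as.data.frame(ev$right)
  expect_equal(nrow(right), 1)
  expect_equal(right$type, 0L)                 # bifurcation, no position
  expect_equal(right$nucleotide, substr(tail1, 1, 1))
  expect_true(is.na(right$position))
  expect_identical(decode_read(substr(read, 1, K), 0, nchar(read), ev, g), read)
})

test_that("a read with an error every k bases cannot be anchored", {
  read <- substr(GENOME, 101, 144)
  for (p in seq(6, nchar(read), by = 8)) { # < k apart, every window hit
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), substr(read, p, p))[1]
  }
  expect_null(select_anchor(read, anchor_dict(K), GRAPH))
})

test_that("truncated event lists are detected at decode time", {
  # a true bifurcation needs a symbol; decoding without one must fail
  prefix <- substr(GENOME, 1, 60)
  v1 <- paste0(prefix, "A", generate_genome(40, 162))
  v2 <- paste0(prefix, "C", generate_genome(40, 163))
  g <- toy_graph(unique(c(oracle_kmerize(v1, K), oracle_kmerize(v2, K))),
                 K, bits = 24L)
  read <- substr(v1, 41, 90)
  ev <- encode_read(read, 0, g)
  expect_equal(nrow(as.data.frame(ev$right)), 1) # the branch symbol
  empty <- list(type = integer(0), nucleotide = character(0),
                position = integer(0))
  expect_error(
    decode_read(substr(read, 1, K), 0, nchar(read),
                list(right = empty, left = empty), g),
    "exhausted")
})

test_that("block codec round-trips simulated reads, N's and degenerate lengths", {
  g_seq <- generate_genome(5000, 64)
  rec <- simulate_reads(g_seq, coverage = 15, read_length = 90,
                        substitution_rate = 0.02, seed = 65)
  k <- 15L
  tab <- count_kmers(rec$sequence, k)
  graph <- build_graph(solid_kmers(tab, 2), 12)
  seqs <- c(rec$sequence[1:500],
            "", "A", "ACGT",                       # shorter than k -> raw
            paste(rep("N", 40), collapse = ""),    # all N
            sub("^(.{20}).", "\\1N", rec$sequence[501:520])) # interior N
  dict <- anchor_dict(k)
  streams <- readbloom:::.rb_encode_block(seqs, dict$ptr, graph$ptr)
  expect_gte(streams$n_raw, 4)
  back <- readbloom:::.rb_decode_block(streams, length(seqs), dict$ptr, graph$ptr)
  expect_identical(back, seqs)
})

test_that("positional events coincide with planted substitutions", {
  g_seq <- generate_genome(20000, 66)
  rec <- simulate_reads(g_seq, coverage = 70, read_length = 100,
                        substitution_rate = 0.01, seed = 67)
  k <- 21L
  tab <- count_kmers(rec$sequence, k)
  t_sol <- infer_solidity_threshold(kmer_histogram(tab))
  solid <- solid_kmers(tab, t_sol)
  graph <- build_graph(solid, 12)
  truth <- attr(rec, "error_pos")
  dict <- anchor_dict(k)
  hits <- misses <- 0L
  for (i in seq_len(400)) {
    a <- select_anchor(rec$sequence[i], dict, graph, solid)
    if (is.null(a)) next
    ev <- encode_read(rec$sequence[i], a$position, graph)
    pos <- c(as.data.frame(ev$right)$position, as.data.frame(ev$left)$position)
    pos <- pos[!is.na(pos)]
    hits <- hits + sum(pos %in% truth[[i]])
    misses <- misses + sum(!pos %in% truth[[i]])
  }
  expect_gt(hits, 100) # the sample actually exercised the path
  expect_gte(hits / (hits + misses), 0.95)
})

test_that("unanchored reads are rare at high coverage", {
  g_seq <- generate_genome(10000, 68)
  rec <- simulate_reads(g_seq, coverage = 70, read_length = 100,
                        substitution_rate = 0.01, seed = 69)
  s <- rb_compress_records(rec, tempfile(), k = 21)
  expect_lt(s$n_raw_reads / s$n_reads, 0.05)
})
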
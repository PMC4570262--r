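K <- 11L
GENOME_Q <- generate_genome(300, 71)
GRAPH_Q <- toy_graph(genome_kmers(GENOME_Q, K), K, bits = 20L)

test_that("sigma rule: 2 up to delta 10, then delta - 5", {
  expect_equal(qual_sigma("8"), 2L)        # delta = 8
  expect_equal(qual_sigma("0"), 11L)       # delta = 16 -> 16 - 5
  expect_equal(qual_sigma("I"), 2L)        # above the cap, delta < 0
  expect_equal(qual_sigma("6"), 2L)        # delta = 10, boundary
  expect_equal(qual_sigma("5"), 6L)        # delta = 11, first delta - 5
  # vectorized over a quality string
  expect_equal(qual_sigma("85"), c(2L, 6L))
})

test_that("solid coverage counts the overlapping present windows", {
  read <- substr(GENOME_Q, 41, 140)
  cov <- solid_coverage(read, GRAPH_Q)
  l <- nchar(read)
  # clean read: coverage i = number of windows containing i, all present
  expected <- vapply(seq_len(l) - 1L, function(i) {
    min(i, l - K) - max(0L, i - K + 1L) + 1L
  }, integer(1))
  expect_equal(cov, expected)
  expect_equal(cov[1], 1L)      # first base: a single window
  expect_equal(cov[K + 1], K)   # interior: k windows
  # substitution kills every window over the error position
  p <- 50L
  substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), substr(read, p, p))[1]
  cov2 <- solid_coverage(read, GRAPH_Q)
  expect_equal(cov2[p], 0L)
  # reads shorter than k have zero coverage
  expect_equal(solid_coverage("ACGT", GRAPH_Q), rep(0L, 4))
})

test_that("smoothing caps, replaces supported positions, keeps error evidence", {
  read <- substr(GENOME_Q, 41, 140)
  l <- nchar(read)
  # step 1: qualities above '@' are truncated even without coverage
  hi <- paste(rep("I", l), collapse = "")
  sm <- smooth_qualities(hi, read, GRAPH_Q)
  expect_false(grepl("[^@]", sm))
  # clean covered read, all qualities <= '@', delta <= 10: everything becomes
  # '@' except the two terminal bases (coverage 1 < sigma = 2)
  q <- paste(rep("8", l), collapse = "")
  sm <- smooth_qualities(q, read, GRAPH_Q)
  expect_equal(substr(sm, 2, l - 1), paste(rep("@", l - 2), collapse = ""))
  expect_equal(substr(sm, 1, 1), "8")
  expect_equal(substr(sm, l, l), "8")
  # a low-quality base at an uncovered error position keeps its value
  p <- 50L
  bad <- read
  substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), substr(bad, p, p))[1]
  sm <- smooth_qualities(q, bad, GRAPH_Q)
  expect_equal(substr(sm, p, p), "8")
})

test_that("smoothing is idempotent and never degrades below min(q, cap)", {
  g_seq <- generate_genome(4000, 72)
  rec <- simulate_reads(g_seq, coverage = 30, read_length = 80,
                        substitution_rate = 0.02, seed = 73)
  k <- 15L
  tab <- count_kmers(rec$sequence, k)
  graph <- build_graph(solid_kmers(tab, 3), 12)
  sm1 <- smooth_qualities(rec$quality, rec$sequence, graph)
  sm2 <- smooth_qualities(sm1, rec$sequence, graph)
  expect_identical(sm2, sm1)
  orig <- utf8ToInt(paste(rec$quality, collapse = ""))
  out <- utf8ToInt(paste(sm1, collapse = ""))
  cap <- utf8ToInt("@")
  expect_true(all(out <= cap))                 # nothing above the cap
  expect_true(all(out >= pmin(orig, cap)))     # never lowered below min(q, cap)
})

test_that("more errors leave more positions unsmoothed", {
  g_seq <- generate_genome(4000, 74)
  frac_smoothed <- vapply(c(0.005, 0.05), function(rate) {
    rec <- simulate_reads(g_seq, coverage = 40, read_length = 80,
                          substitution_rate = rate, seed = 75)
    tab <- count_kmers(rec$sequence, 15L)
    t_sol <- infer_solidity_threshold(kmer_histogram(tab))
    graph <- build_graph(solid_kmers(tab, t_sol), 12)
    sm <- smooth_qualities(rec$quality, rec$sequence, graph)
    mean(utf8ToInt(paste(sm, collapse = "")) == utf8ToInt("@"))
  }, numeric(1))
  expect_gt(frac_smoothed[1], frac_smoothed[2])
})

test_that("quality stream: zlib round trip and near-constant input", {
  quals <- rep(paste(rep("@", 100), collapse = ""), 10000)
  z <- readbloom:::compress_quality_stream(quals)
  expect_lt(length(z), 5000) # a million identical bytes
  back <- readbloom:::decompress_quality_stream(z, nchar(quals))
  expect_identical(back, quals)
  # mixed lengths, including empty
  set.seed(76)
  quals <- vapply(sample(0:50, 200, TRUE), function(l) {
    paste(sample(strsplit(rawToChar(as.raw(33:74)), "")[[1L]], l, TRUE),
          collapse = "")
  }, character(1))
  z <- readbloom:::compress_quality_stream(quals)
  expect_identical(readbloom:::decompress_quality_stream(z, nchar(quals)), quals)
  expect_error(readbloom:::decompress_quality_stream(z, rev(nchar(quals) + 1L)),
               "corrupt")
})
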
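test_that("canonical counting matches the brute-force oracle", {
  # both 3-mers of ACGT canonicalize to ACG, so two copies give count 4
  tab <- count_kmers(c("ACGT", "ACGT"), 3)
  expect_equal(kmer_count(tab, "ACG"), 4)
  expect_equal(kmer_count(tab, "CGT"), 4) # same canonical class
  st <- .rb_count_stats(tab$ptr)
  expect_equal(st$n_distinct, 1)

  set.seed(21)
  reads <- random_dna(30, 40)
  k <- 7L
  tab <- count_kmers(reads, k)
  expected <- oracle_count_kmers(reads, k)
  expect_equal(.rb_count_stats(tab$ptr)$n_distinct, length(expected))
  expect_equal(kmer_count(tab, names(expected)), unname(as.numeric(expected)))
})

test_that("kmer windows overlapping N are skipped", {
  tab <- count_kmers("AANGT", 3)
  expect_equal(.rb_count_stats(tab$ptr)$n_distinct, 0)
  tab <- count_kmers("AACNGAT", 3)   # AAC before N, GAT after
  expect_equal(.rb_count_stats(tab$ptr)$n_distinct, 2)
  # a single clean read of length l contributes l-k+1 kmers in total
  tab <- count_kmers(random_dna(1, 50), 11)
  expect_equal(.rb_count_stats(tab$ptr)$total, 40)
})

test_that("abundance histogram tallies distinct kmers per count", {
  tab <- count_kmers(c("ACGT", "ACGT"), 3)
  h <- kmer_histogram(tab)
  expect_equal(h, data.frame(abundance = 4L, n_kmers = 1))
  expect_equal(nrow(kmer_histogram(count_kmers(character(0), 3))), 0)
  # sum over the histogram = number of distinct kmers
  set.seed(22)
  tab <- count_kmers(random_dna(50, 60), 9)
  h <- kmer_histogram(tab)
  expect_equal(sum(h$n_kmers), .rb_count_stats(tab$ptr)$n_distinct)
})

test_that("solidity threshold lands at the first inter-peak valley", {
  h <- data.frame(abundance = c(1L, 2L, 50L), n_kmers = c(1000, 10, 500))
  expect_equal(infer_solidity_threshold(h), 2L)
  # monotone decreasing histogram (no coverage peak): fallback
  h <- data.frame(abundance = 1:6, n_kmers = c(5000, 800, 300, 100, 40, 10))
  expect_equal(infer_solidity_threshold(h), 3L)
  # valley beyond the clamp range is clamped
  h <- data.frame(abundance = c(1L, 25L, 60L), n_kmers = c(1000, 5, 300))
  expect_equal(infer_solidity_threshold(h), 20L)
  expect_error(infer_solidity_threshold(data.frame()), "empty")
})

test_that("threshold inference separates error and genomic peaks", {
  # simulated 70x with 1 % errors: bimodal histogram, threshold in [2, 10],
  # and the solid set recovers nearly all genomic kmers
  g <- generate_genome(20000, 31)
  rec <- simulate_reads(g, coverage = 70, read_length = 100,
                        substitution_rate = 0.01, seed = 32)
  k <- 21L
  tab <- count_kmers(rec$sequence, k)
  t_sol <- infer_solidity_threshold(kmer_histogram(tab))
  expect_gte(t_sol, 2L)
  expect_lte(t_sol, 10L)
  solid <- solid_kmers(tab, t_sol)
  truth <- genome_kmers(g, k)
  expect_gte(mean(solid_contains(solid, truth)), 0.99)
})

test_that("solid set obeys the threshold and is antitone in T_sol", {
  tab <- count_kmers(c("ACGTACGT", "ACGTACGT", "TTTTT"), 5)
  s1 <- solid_kmers(tab, 1)
  expect_equal(solid_size(s1), .rb_count_stats(tab$ptr)$n_distinct)
  s2 <- solid_kmers(tab, 2)
  expect_true(all(solid_contains(s1, solid_as_character(s2))))
  expect_false(solid_contains(s2, "TTTTT")) # count 1 < 2
  expect_true(solid_contains(s2, "ACGTA"))  # count >= 2 (inclusive threshold)
  sizes <- vapply(1:5, function(t) solid_size(solid_kmers(tab, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # agreement with the brute-force filter on random reads
  set.seed(23)
  reads <- random_dna(40, 50)
  tab <- count_kmers(reads, 9)
  expected <- oracle_count_kmers(reads, 9)
  for (t_sol in c(1L, 2L, 3L)) {
    want <- sort(names(expected[expected >= t_sol]))
    expect_identical(sort(solid_as_character(solid_kmers(tab, t_sol))), want)
  }
})

test_that("error-free reads at sufficient coverage recover the genome kmers", {
  g <- generate_genome(3000, 33)
  rec <- simulate_reads(g, coverage = 20, read_length = 80,
                        substitution_rate = 0, seed = 34)
  tab <- count_kmers(rec$sequence, 21)
  solid <- solid_kmers(tab, 3)
  truth <- genome_kmers(g, 21)
  got <- solid_as_character(solid)
  expect_true(all(got %in% truth))
  expect_gte(length(got) / length(truth), 0.99) # a few edge kmers undersampled
})
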
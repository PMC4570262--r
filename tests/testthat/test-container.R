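test_that("lossless FASTQ round trip is byte-identical on disk", {
  f <- tempfile(fileext = ".fastq")
  rb_simulate(f, genome_length = 8000, coverage = 25, read_length = 90,
              substitution_rate = 0.01, seed = 91)
  cont <- tempfile(fileext = ".rbf")
  back <- tempfile(fileext = ".fastq")
  s <- rb_compress(f, cont, k = 21, lossless_qual = TRUE)
  rb_decompress(cont, back)
  expect_identical(readBin(back, "raw", file.size(back)),
                   readBin(f, "raw", file.size(f)))
  expect_gt(s$ratio, 1)
  expect_equal(s$n_reads, ceiling(8000 * 25 / 90))
})

test_that("lossy mode: headers and sequences exact, qualities only smoothed", {
  f <- tempfile(fileext = ".fastq")
  rb_simulate(f, genome_length = 8000, coverage = 25, read_length = 90,
              substitution_rate = 0.01, seed = 92)
  orig <- read_fastx(f)
  cont <- tempfile()
  s_lossy <- rb_compress(f, cont, k = 21)
  rec <- rb_decompress_records(cont)
  expect_identical(rec$header, orig$header)
  expect_identical(rec$sequence, orig$sequence)
  q_out <- utf8ToInt(paste(rec$quality, collapse = ""))
  q_in <- utf8ToInt(paste(orig$quality, collapse = ""))
  cap <- utf8ToInt("@")
  expect_true(all(q_out <= cap))
  changed <- q_out != q_in
  # every change is either the cap truncation or a smooth-to-cap
  expect_true(all(q_out[changed] == cap))
  # smoothing pays: lossy file smaller than lossless
  s_lossless <- rb_compress(f, tempfile(), k = 21, lossless_qual = TRUE)
  expect_lt(s_lossy$compressed_bytes, s_lossless$compressed_bytes)
})

test_that("FASTA input round-trips without a quality stream", {
  f <- tempfile(fileext = ".fa")
  g_seq <- generate_genome(6000, 93)
  rec <- simulate_reads(g_seq, coverage = 15, read_length = 80,
                        substitution_rate = 0.005, seed = 94)
  fa <- read_set(rec$header, rec$sequence)
  write_fastx(fa, f)
  cont <- tempfile()
  s <- rb_compress(f, cont, k = 21)
  expect_equal(s$stream_bytes[["quality"]], 0)
  back <- rb_decompress_records(cont)
  expect_identical(back$format, "fasta")
  expect_identical(back$header, fa$header)
  expect_identical(back$sequence, fa$sequence)
})

test_that("decompression is self-contained and never counts kmers", {
  f <- tempfile(fileext = ".fastq")
  rb_simulate(f, genome_length = 4000, coverage = 20, read_length = 70,
              substitution_rate = 0.01, seed = 95)
  cont <- tempfile()
  rb_compress(f, cont, k = 17, lossless_qual = TRUE)
  # move the container elsewhere and delete the input: still decodable
  cont2 <- tempfile()
  file.copy(cont, cont2)
  orig_lines <- readLines(f)
  unlink(f)
  calls_before <- readbloom:::.rb_state$count_calls
  out <- tempfile(fileext = ".fastq")
  rb_decompress(cont2, out)
  expect_identical(readLines(out), orig_lines)
  expect_identical(readbloom:::.rb_state$count_calls, calls_before)
})

test_that("corruption is detected by the trailing checksum", {
  f <- tempfile(fileext = ".fastq")
  rb_simulate(f, genome_length = 2000, coverage = 10, read_length = 60,
              substitution_rate = 0.01, seed = 96)
  cont <- tempfile()
  rb_compress(f, cont, k = 17)
  bytes <- readBin(cont, "raw", file.size(cont))
  bytes[length(bytes) %/% 2] <- xor(bytes[length(bytes) %/% 2], as.raw(0xFF))
  writeBin(bytes, cont)
  expect_error(rb_decompress_records(cont), "checksum")
  expect_error(rb_decompress_records(f), "magic|corrupt")
})

test_that("multi-block files decode block by block", {
  f <- tempfile(fileext = ".fastq")
  rb_simulate(f, genome_length = 5000, coverage = 20, read_length = 80,
              substitution_rate = 0.01, seed = 97)
  cont <- tempfile()
  s <- rb_compress(f, cont, k = 21, lossless_qual = TRUE, block_size = 300)
  expect_gt(s$n_blocks, 3)
  back <- tempfile()
  rb_decompress(cont, back)
  expect_identical(readLines(back), readLines(f))
})

test_that("seq-only mode keeps sequences and drops the rest", {
  f <- tempfile(fileext = ".fastq")
  rb_simulate(f, genome_length = 3000, coverage = 15, read_length = 70,
              substitution_rate = 0.01, seed = 98)
  orig <- read_fastx(f)
  cont <- tempfile()
  s <- rb_compress(f, cont, k = 17, seq_only = TRUE)
  expect_equal(s$stream_bytes[["headers"]], 0)
  expect_equal(s$stream_bytes[["quality"]], 0)
  back <- rb_decompress_records(cont)
  expect_identical(back$sequence, orig$sequence)
})

test_that("degenerate inputs still round-trip (all reads shorter than k)", {
  rec <- read_set(c("a", "b", "c"), c("ACGT", "NNN", ""),
                  c("IIII", "!!!", ""))
  cont <- tempfile()
  s <- rb_compress_records(rec, cont, k = 31, lossless_qual = TRUE)
  expect_equal(s$n_raw_reads, 3L)
  back <- rb_decompress_records(cont)
  expect_identical(back[1:3], rec[1:3])
})

test_that("explicit abundance threshold is honoured", {
  g_seq <- generate_genome(3000, 99)
  rec <- simulate_reads(g_seq, coverage = 20, read_length = 70,
                        substitution_rate = 0.01, seed = 100)
  cont <- tempfile()
  s <- rb_compress_records(rec, cont, k = 17, t_sol = 5)
  expect_equal(s$t_sol, 5L)
  back <- rb_decompress_records(cont)
  expect_identical(back$sequence, rec$sequence)
})

test_that("the CLI drives compress, decompress and simulate", {
  fq <- tempfile(fileext = ".fastq")
  suppressMessages(rb_cli(c("simulate", "-o", fq, "--genome-length", "2000",
                            "--coverage", "10", "--read-length", "60",
                            "--seed", "5")))
  expect_true(file.exists(fq))
  cont <- tempfile()
  out <- tempfile(fileext = ".fastq")
  suppressMessages({
    rb_cli(c("compress", "-i", fq, "-o", cont, "-k", "17",
             "--lossless-qual"))
    rb_cli(c("decompress", "-i", cont, "-o", out))
  })
  expect_identical(readLines(out), readLines(fq))
  expect_error(rb_cli(c("frobnicate")), "unknown subcommand")
})
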
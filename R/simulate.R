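#' Generate a uniform random genome
#'
#' I.i.d. uniform A/C/G/T from a dedicated deterministic generator: the
#' same (length, seed) pair always yields the same string, independent
#' of R's RNG state.  An optional tandem repeat copies a segment back
#' into the genome to create true graph branch points.
#'
#' @param length genome length in bp.
#' @param seed integer seed.
#' @param repeat_fraction optional fraction (0 to 0.5) of the genome to
#'   duplicate: the first `repeat_fraction * length` bases are copied
#'   over the last ones, creating an exact repeat.
#' @return a DNA string.
#' @export
generate_genome <- function(length, seed, repeat_fraction = 0) {
  g <- .rb_gen_genome(as.numeric(length), as.integer(seed))
  if (repeat_fraction > 0) {
    stopifnot(repeat_fraction <= 0.5)
    n <- nchar(g)
    r <- floor(n * repeat_fraction)
    if (r >= 1)
      substr(g, n - r + 1L, n) <- substr(g, 1L, r)
  }
  g
}

#' Simulate an error-bearing short-read set with ground truth
#'
#' Draws `ceiling(coverage * G / read_length)` reads at uniform random
#' start positions, half of them reverse-complemented.  Each base is
#' substituted with probability `substitution_rate` by a uniformly
#' chosen different base.  Qualities follow a linear per-position mean
#' Phred profile (default 38 falling to 32, Gaussian noise sd 3,
#' clamped to 2..40 — an Illumina-like profile); erroneous bases get a
#' quality from the low tail (Phred 2..15).  Headers
#' `sim.<i> <pos>/<F|R>` carry the true origin; planted error positions
#' (1-based) are returned in `error_pos`.
#'
#' @param genome DNA string, e.g. from [generate_genome()].
#' @param coverage mean sequencing depth.
#' @param read_length read length in bp (<= genome length).
#' @param substitution_rate per-base substitution probability.
#' @param seed integer seed; same inputs give a byte-identical read set.
#' @param quality_profile numeric `c(mean_start, mean_end, sd)`.
#' @return a [read_set()] with an `error_pos` attribute (list of
#'   integer vectors, one per read).
#' @export
simulate_reads <- function(genome, coverage = 70, read_length = 100L,
                           substitution_rate = 0.01, seed = 1L,
                           quality_profile = c(38, 32, 3)) {
  sim <- .rb_sim_reads(genome, coverage, as.integer(read_length),
                       substitution_rate, as.integer(seed),
                       quality_profile[1L], quality_profile[2L],
                       quality_profile[3L])
  out <- read_set(sim$header, sim$sequence, sim$quality)
  attr(out, "error_pos") <- sim$error_pos
  out
}

#' Simulate a read set and write it to FASTQ
#'
#' Convenience wrapper used by tests, the CLI and the acceptance script.
#'
#' @param path output FASTQ path.
#' @param genome_length genome size in bp.
#' @param coverage,read_length,substitution_rate,quality_profile passed
#'   to [simulate_reads()].
#' @param seed integer seed (genome uses `seed`, reads `seed + 1`).
#' @return invisibly, list with `path`, `genome` and the `read_set`.
#' @export
rb_simulate <- function(path, genome_length = 1e6, coverage = 70,
                        read_length = 100L, substitution_rate = 0.01,
                        seed = 1L, quality_profile = c(38, 32, 3)) {
  genome <- generate_genome(genome_length, seed)
  records <- simulate_reads(genome, coverage, read_length,
                            substitution_rate, seed + 1L, quality_profile)
  write_fastx(records, path)
  invisible(list(path = path, genome = genome, records = records))
}
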
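# On-disk container (byte layout in inst/FORMAT.md).  All integers are
# little-endian; every component symbol stream is entropy-coded with its own
# order-0 model, freshly initialized per block so blocks decode independently.

SEQ_STREAMS <- c(mode = 2L, len = 256L, aidx = 256L, apos = 256L, nbr = 256L,
                 nbl = 256L, btype = 2L, bnt = 4L, bpos = 256L, nn = 256L,
                 npos = 256L, raw = 5L)
HDR_STREAMS <- c(hntok = 256L, hop = 3L, hdelta = 256L, hplen = 256L,
                 hslen = 256L, hchar = 256L)

CONTAINER_MAGIC <- "RBF1"
CONTAINER_VERSION <- 1L

encode_stream_section <- function(symbols, alphabet) {
  n <- length(symbols)
  if (n == 0L) return(c(u64_raw(0), u64_raw(0)))
  bytes <- arith_encode(symbols, alphabet)
  c(u64_raw(n), u64_raw(length(bytes)), bytes)
}

# sequential raw-vector reader
make_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$pos <- 0L
  env$bytes <- bytes
  env
}

take <- function(rd, n) {
  n <- as.integer(n)
  if (rd$pos + n > length(rd$bytes)) stop("container corrupt: unexpected end of file")
  out <- rd$bytes[rd$pos + seq_len(n)]
  rd$pos <- rd$pos + n
  out
}

take_u64 <- function(rd) raw_u64(take(rd, 8L))
take_u32 <- function(rd) raw_u32(take(rd, 4L))

decode_stream_section <- function(rd, alphabet) {
  n <- take_u64(rd)
  nb <- take_u64(rd)
  if (n == 0) return(integer(0))
  arith_decode(take(rd, nb), n, alphabet)
}

#' Compress an in-memory read set into a container file
#'
#' Two passes over the reads: pass 1 counts canonical kmers, infers the
#' solidity threshold from the abundance histogram (unless given) and
#' builds the Bloom-filter de Bruijn graph; pass 2 encodes each block of
#' reads against the graph into component symbol streams.  Memory is
#' governed by the number of solid kmers (roughly the genome size), not
#' by the file size.
#'
#' @param records a [read_set()].
#' @param output path of the container file to write.
#' @param k kmer length (1 to 31); default 31.
#' @param t_sol solidity threshold: `"auto"` (inferred from the kmer
#'   abundance histogram) or an integer >= 1.
#' @param bits_per_kmer Bloom filter bits per solid kmer; default 12.
#' @param lossless_qual keep quality strings byte-exact instead of the
#'   default lossy solid-kmer smoothing.
#' @param seq_only drop header and quality streams (sequences only).
#' @param block_size reads per independently decodable block.
#' @return invisibly, a summary list: read counts, chosen parameters,
#'   per-component compressed byte counts and the overall compression
#'   ratio (original size / compressed size).
#' @export
rb_compress_records <- function(records, output, k = 31L, t_sol = "auto",
                                bits_per_kmer = 12L, lossless_qual = FALSE,
                                seq_only = FALSE, block_size = 50000L) {
  stopifnot(inherits(records, "read_set"))
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be in 1..31")
  bits_per_kmer <- as.integer(bits_per_kmer)
  if (bits_per_kmer < 1L || bits_per_kmer > 64L)
    stop("bits_per_kmer must be in 1..64")
  n_reads <- length(records$sequence)
  if (n_reads == 0L) stop("input contains no reads")
  is_fastq <- records$format == "fastq"
  blocks <- split(seq_len(n_reads),
                  ceiling(seq_len(n_reads) / as.integer(block_size)))

  # pass 1: count kmers, choose threshold, build the graph
  tab <- count_kmers(character(0), k)
  for (idx in blocks) count_kmers_add(tab, records$sequence[idx])
  hist <- kmer_histogram(tab)
  auto <- identical(t_sol, "auto")
  t_sol_used <- if (auto) {
    if (nrow(hist)) infer_solidity_threshold(hist) else 1L
  } else as.integer(t_sol)
  solid <- solid_kmers(tab, t_sol_used)
  if (solid_size(solid) == 0 && auto && t_sol_used > 1L) {
    t_sol_used <- 1L # degenerate input: keep every kmer rather than fail
    solid <- solid_kmers(tab, t_sol_used)
  }
  have_solid <- solid_size(solid) > 0
  graph <- if (have_solid) {
    build_graph(solid, bits_per_kmer)
  } else {
    # no kmer at all (e.g. every read shorter than k): empty filter, all
    # queries answer absent, every read is stored raw
    structure(list(ptr = .rb_bloom_empty(8, 1L, k), k = k,
                   bits_per_kmer = bits_per_kmer), class = "probabilistic_dbg")
  }
  solid_ptr <- if (have_solid) solid$ptr else NULL
  rm(tab)

  # pass 2: encode blocks
  dict <- anchor_dict(k)
  n_raw_reads <- 0L
  seq_bytes <- hdr_bytes <- qual_bytes <- 0
  block_sections <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    streams <- .rb_encode_block(records$sequence[idx], dict$ptr, graph$ptr,
                                solid_ptr)
    n_raw_reads <- n_raw_reads + streams$n_raw
    sec <- list(u32_raw(length(idx)))
    for (nm in names(SEQ_STREAMS)) {
      enc <- encode_stream_section(streams[[nm]], SEQ_STREAMS[[nm]])
      seq_bytes <- seq_bytes + length(enc)
      sec[[length(sec) + 1L]] <- enc
    }
    if (!seq_only) {
      hstreams <- encode_headers(records$header[idx])
      for (nm in names(HDR_STREAMS)) {
        enc <- encode_stream_section(hstreams[[nm]], HDR_STREAMS[[nm]])
        hdr_bytes <- hdr_bytes + length(enc)
        sec[[length(sec) + 1L]] <- enc
      }
      if (is_fastq) {
        q <- records$quality[idx]
        if (!lossless_qual)
          q <- smooth_qualities(q, records$sequence[idx], graph)
        qz <- compress_quality_stream(q)
        qual_bytes <- qual_bytes + length(qz) + 8L
        sec[[length(sec) + 1L]] <- c(u64_raw(length(qz)), qz)
      }
    }
    block_sections[[bi]] <- unlist(sec)
  }

  flags <- as.integer(is_fastq) + 2L * as.integer(lossless_qual) +
    4L * as.integer(seq_only)
  bloom_raw <- dbg_serialize(graph)
  dict_syms <- .rb_dict_symbols(dict$ptr)
  dict_raw <- c(u64_raw(dict_size(dict)), encode_stream_section(dict_syms, 4L))

  body <- c(charToRaw(CONTAINER_MAGIC), as.raw(CONTAINER_VERSION),
            as.raw(flags), as.raw(k), u32_raw(t_sol_used),
            as.raw(bits_per_kmer), u64_raw(n_reads),
            u64_raw(length(bloom_raw)), bloom_raw,
            u64_raw(length(dict_raw)), dict_raw,
            u32_raw(length(blocks)), unlist(block_sections))
  out <- c(body, u32_raw(.rb_crc32(body)))
  writeBin(out, output)

  original <- fastx_bytes(records)
  invisible(list(
    n_reads = n_reads, n_blocks = length(blocks), k = k, t_sol = t_sol_used,
    bits_per_kmer = bits_per_kmer, n_anchors = dict_size(dict),
    n_raw_reads = n_raw_reads,
    stream_bytes = c(bloom = length(bloom_raw), dict = length(dict_raw),
                     sequence = seq_bytes, headers = hdr_bytes,
                     quality = qual_bytes),
    # the DNA component of the file (graph + anchors + sequence streams),
    # the quantity the coverage and read-order experiments look at
    dna_bytes = length(bloom_raw) + length(dict_raw) + seq_bytes,
    original_bytes = original, compressed_bytes = length(out),
    ratio = original / length(out)))
}

#' Decompress a container file into an in-memory read set
#'
#' Loads the serialized de Bruijn graph and anchor dictionary, then
#' replays each read's walk.  No kmer counting happens on this path,
#' and nothing but the container file itself is needed.
#'
#' @param input container file written by [rb_compress_records()].
#' @return a [read_set()].
#' @export
rb_decompress_records <- function(input) {
  bytes <- readBin(input, "raw", n = file.size(input))
  if (length(bytes) < 30L) stop("container corrupt: file too short")
  crc_stored <- raw_u32(bytes[length(bytes) - 3:0])
  body <- bytes[seq_len(length(bytes) - 4L)]
  if (.rb_crc32(body) != crc_stored)
    stop("container corrupt: checksum mismatch")
  rd <- make_reader(body)
  if (rawToChar(take(rd, 4L)) != CONTAINER_MAGIC)
    stop("not a readbloom container (bad magic)")
  if (as.integer(take(rd, 1L)) != CONTAINER_VERSION)
    stop("unsupported container version")
  flags <- as.integer(take(rd, 1L))
  is_fastq <- bitwAnd(flags, 1L) > 0L
  seq_only <- bitwAnd(flags, 4L) > 0L
  k <- as.integer(take(rd, 1L))
  take_u32(rd)                      # t_sol (informational)
  take(rd, 1L)                      # bits_per_kmer (informational)
  n_reads <- take_u64(rd)

  graph <- dbg_deserialize(take(rd, take_u64(rd)))
  dict_rd <- make_reader(take(rd, take_u64(rd)))
  n_anchors <- take_u64(dict_rd)
  dict_syms <- decode_stream_section(dict_rd, 4L)
  if (length(dict_syms) != n_anchors * k)
    stop("container corrupt: anchor dictionary length")
  dict_ptr <- .rb_dict_from_symbols(dict_syms, k)

  n_blocks <- take_u32(rd)
  headers <- seqs <- quals <- vector("list", n_blocks)
  for (bi in seq_len(n_blocks)) {
    nb <- take_u32(rd)
    streams <- lapply(SEQ_STREAMS, function(a) NULL)
    for (nm in names(SEQ_STREAMS))
      streams[[nm]] <- decode_stream_section(rd, SEQ_STREAMS[[nm]])
    seqs[[bi]] <- .rb_decode_block(streams, nb, dict_ptr, graph$ptr)
    if (!seq_only) {
      hstreams <- lapply(HDR_STREAMS, function(a) NULL)
      for (nm in names(HDR_STREAMS))
        hstreams[[nm]] <- decode_stream_section(rd, HDR_STREAMS[[nm]])
      headers[[bi]] <- decode_headers(hstreams, nb)
      if (is_fastq)
        quals[[bi]] <- decompress_quality_stream(take(rd, take_u64(rd)),
                                                 nchar(seqs[[bi]]))
    }
  }
  seqs <- unlist(seqs, use.names = FALSE)
  if (length(seqs) != n_reads)
    stop("container corrupt: read count mismatch")
  if (seq_only) {
    read_set(as.character(seq_len(n_reads)), seqs)
  } else if (is_fastq) {
    read_set(unlist(headers, use.names = FALSE), seqs,
             unlist(quals, use.names = FALSE))
  } else {
    read_set(unlist(headers, use.names = FALSE), seqs)
  }
}

#' Compress a FASTQ/FASTA file
#'
#' File-level wrapper around [rb_compress_records()]: reads the input
#' (gzip accepted transparently), compresses it into the self-contained
#' container and reports per-component sizes and the overall ratio
#' (original size / compressed size).
#'
#' @inheritParams rb_compress_records
#' @param input path to a FASTQ or FASTA file, optionally gzipped.
#' @return the summary list of [rb_compress_records()], invisibly.
#' @examples
#' \donttest{
#' sim <- rb_simulate(tempfile(fileext = ".fastq"), genome_length = 5e4,
#'                    coverage = 30, seed = 7)
#' out <- tempfile(fileext = ".rbf")
#' summary <- rb_compress(sim$path, out)
#' summary$ratio
#' }
#' @export
rb_compress <- function(input, output, k = 31L, t_sol = "auto",
                        bits_per_kmer = 12L, lossless_qual = FALSE,
                        seq_only = FALSE, block_size = 50000L) {
  records <- read_fastx(input)
  rb_compress_records(records, output, k = k, t_sol = t_sol,
                      bits_per_kmer = bits_per_kmer,
                      lossless_qual = lossless_qual, seq_only = seq_only,
                      block_size = block_size)
}

#' Decompress a container file to FASTQ/FASTA
#'
#' @param input container file.
#' @param output path for the reconstructed FASTQ (or FASTA) file.
#' @return invisibly, a list with the read count and output path.
#' @export
rb_decompress <- function(input, output) {
  records <- rb_decompress_records(input)
  write_fastx(records, output)
  invisible(list(n_reads = length(records$sequence), output = output))
}
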
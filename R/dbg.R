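#' Build the probabilistic de Bruijn graph
#'
#' Inserts the solid canonical kmers into a Bloom filter of
#' `m = bits_per_kmer * n_solid` bits (rounded up to a whole byte) with
#' `h = round(bits_per_kmer * ln 2)` hash functions (at least 1).  Node
#' membership is membership of the canonical kmer in the filter; edges
#' are inferred by querying the four possible successors of a node.  The
#' filter has one-sided error: inserted kmers always answer present,
#' non-members answer present with probability roughly
#' `(1 - exp(-h n / m))^h` (about 0.3 % at 12 bits/kmer).  False
#' positives only cost extra bifurcation symbols, never correctness.
#'
#' @param solid a [solid_kmers()] set (must be non-empty).
#' @param bits_per_kmer Bloom bits per solid kmer; default 12.
#' @return an object of class `probabilistic_dbg`.
#' @export
build_graph <- function(solid, bits_per_kmer = 12) {
  stopifnot(inherits(solid, "solid_kmer_set"))
  ptr <- .rb_bloom_build(solid$ptr, bits_per_kmer)
  structure(list(ptr = ptr, k = solid$k, bits_per_kmer = bits_per_kmer),
            class = "probabilistic_dbg")
}

#' @export
print.probabilistic_dbg <- function(x, ...) {
  p <- .rb_bloom_params(x$ptr)
  cat(sprintf(
    "probabilistic de Bruijn graph: k=%d, %.0f kmers in %.0f-bit Bloom filter (h=%d)\n",
    p$k, p$n_inserted, p$m_bits, p$h))
  invisible(x)
}

#' Query node membership in the graph
#'
#' @param graph a [build_graph()] object.
#' @param kmers character vector of kmers (either strand; the canonical
#'   form is queried).
#' @return logical vector.
#' @export
dbg_contains <- function(graph, kmers) .rb_bloom_contains(graph$ptr, kmers)

#' Graph successors of a node
#'
#' Returns the subset of the four candidate successors whose canonical
#' form is present in the Bloom filter, in A < C < G < T order.
#'
#' @param graph a [build_graph()] object.
#' @param kmer a single kmer string.
#' @return character vector (0 to 4 kmers).
#' @export
dbg_successors <- function(graph, kmer) .rb_bloom_successors(graph$ptr, kmer)

# serialized Bloom header: magic "RBbf", m (u64), h (u8), k (u8),
# seed1 (8 bytes), seed2 (8 bytes), n_inserted (u64), then the bit array
#' Serialize / deserialize the graph
#'
#' The byte-exact round trip is the basis of the self-contained container:
#' decompression rebuilds the identical filter, so every membership query
#' answers exactly as at compression time.
#'
#' @param graph a [build_graph()] object.
#' @return `dbg_serialize()`: a raw vector.
#' @export
dbg_serialize <- function(graph) {
  p <- .rb_bloom_params(graph$ptr)
  c(charToRaw("RBbf"), u64_raw(p$m_bits), as.raw(p$h), as.raw(p$k),
    p$seed1, p$seed2, u64_raw(p$n_inserted), .rb_bloom_bits(graph$ptr))
}

#' @rdname dbg_serialize
#' @param bytes a raw vector produced by `dbg_serialize()`.
#' @export
dbg_deserialize <- function(bytes) {
  if (length(bytes) < 38L || !identical(bytes[1:4], charToRaw("RBbf")))
    stop("not a serialized de Bruijn graph (bad magic)")
  m <- raw_u64(bytes[5:12])
  h <- as.integer(bytes[13])
  k <- as.integer(bytes[14])
  seed1 <- bytes[15:22]
  seed2 <- bytes[23:30]
  n_ins <- raw_u64(bytes[31:38])
  bits <- bytes[-(1:38)]
  if (length(bits) != ceiling(m / 8))
    stop("serialized graph is corrupt: bit-array length mismatch")
  ptr <- .rb_bloom_from_parts(m, h, k, n_ins, seed1, seed2, bits)
  structure(list(ptr = ptr, k = k, bits_per_kmer = NA_real_),
            class = "probabilistic_dbg")
}

#' Memory cost of an exact hash-table de Bruijn graph
#'
#' An exact node-table representation (packed kmer plus one edge byte)
#' costs `8 * ceiling(k / 32) + 1` bytes per node — about 27 GB for the
#' 3e9 nodes of a human-sized genome at k = 31.  The Bloom-filter graph
#' stores the same node set in `bits_per_kmer` bits per node.
#'
#' @param k kmer length.
#' @return bytes per node (numeric).
#' @export
exact_dbg_bytes_per_node <- function(k) 8 * ceiling(k / 32) + 1

# --- little-endian fixed-width helpers (shared with the container) -------

u64_raw <- function(x) {
  out <- raw(8L)
  for (i in 1:8) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_u64 <- function(r) sum(as.numeric(r) * 256^(0:7))

u32_raw <- function(x) u64_raw(x)[1:4]

raw_u32 <- function(r) sum(as.numeric(r) * 256^(0:3))
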
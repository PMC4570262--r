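#' Kmer primitives
#'
#' A kmer is a DNA word of length `k` (1 to 31) over A/C/G/T, packed two
#' bits per base (A=0, C=1, G=2, T=3, most-significant pair = leftmost
#' base).  `kmer_encode()` returns that packed value as a numeric (exact
#' for `k <= 26`); `kmer_decode()` inverts it.  `kmer_canonical()` returns
#' the smaller of a kmer and its reverse complement under the packed
#' integer order, which is also lexicographic order for this encoding.
#'
#' @param kmers character vector of equal-length DNA strings (A/C/G/T).
#' @return `kmer_encode()`: numeric vector of packed values.
#' @examples
#' kmer_encode(c("AAA", "TTT"))   # 0 and 63
#' kmer_canonical("GTT")          # "AAC"
#' @export
kmer_encode <- function(kmers) .rb_kmer_encode(kmers)

#' @rdname kmer_encode
#' @param values numeric vector of packed kmer values.
#' @param k kmer length in bases.
#' @export
kmer_decode <- function(values, k) .rb_kmer_decode(values, as.integer(k))

#' @rdname kmer_encode
#' @export
kmer_revcomp <- function(kmers) .rb_kmer_revcomp(kmers)

#' @rdname kmer_encode
#' @export
kmer_canonical <- function(kmers) .rb_kmer_canonical(kmers)

#' Cut a sequence into its constituent kmers
#'
#' Returns the `l - k + 1` kmers of `seq` in order; a sequence shorter
#' than `k` yields an empty vector (such reads cannot be anchored to the
#' graph and are stored raw).
#'
#' @param seq a single DNA string.
#' @param k kmer length (1 to 31).
#' @return character vector of kmers.
#' @export
kmerize <- function(seq, k) .rb_kmerize(seq, as.integer(k))

#' Successor and predecessor kmers in the de Bruijn graph
#'
#' The four candidate successors of kmer `x` share their first `k - 1`
#' bases with the last `k - 1` bases of `x`; they are returned in
#' A < C < G < T order.  Predecessors are symmetric.
#'
#' @param kmer a single DNA string.
#' @return character vector of 4 kmers.
#' @export
kmer_successors <- function(kmer) .rb_kmer_successors(kmer)

#' @rdname kmer_successors
#' @export
kmer_predecessors <- function(kmer) .rb_kmer_predecessors(kmer)
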
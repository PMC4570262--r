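#' Anchor dictionary
#'
#' Insertion-ordered set of anchor kmers shared across reads, mapping
#' kmer to integer index and back.  Anchors are stored in the read's
#' forward orientation (not canonicalized) so that decoding needs no
#' strand flag.  The dictionary is serialized into the container, so an
#' anchor costs an integer index per read instead of k bases.
#'
#' @param k kmer length.
#' @return an object of class `anchor_dictionary`.
#' @export
anchor_dict <- function(k) {
  structure(list(ptr = .rb_dict_new(as.integer(k)), k = as.integer(k)),
            class = "anchor_dictionary")
}

#' @export
print.anchor_dictionary <- function(x, ...) {
  cat(sprintf("anchor dictionary: k=%d, %.0f anchors\n", x$k, .rb_dict_size(x$ptr)))
  invisible(x)
}

#' @rdname anchor_dict
#' @param dict an `anchor_dictionary`.
#' @export
dict_size <- function(dict) .rb_dict_size(dict$ptr)

#' @rdname anchor_dict
#' @param index 0-based anchor indices.
#' @export
dict_get <- function(dict, index) .rb_dict_get(dict$ptr, as.numeric(index))

#' @rdname anchor_dict
#' @param kmer a single kmer string.
#' @return `dict_find()`: 0-based index, or -1 when absent.
#' @export
dict_find <- function(dict, kmer) .rb_dict_find(dict$ptr, kmer)

#' Select the anchor kmer of a read
#'
#' Scans the read's kmers left to right; the first kmer already in the
#' dictionary wins.  Otherwise the leftmost *solid* kmer (graph
#' membership is the solidity oracle) is appended to the dictionary and
#' becomes the anchor.  A read with no solid kmer — at least one
#' sequencing error every k bases, or a low-coverage region — gets no
#' anchor and is stored raw; reads shorter than k are always raw.
#'
#' Note the dictionary is mutated (grown) as a side effect, mirroring the
#' single pass of the compressor.
#'
#' @param read a DNA string (N-masked: only A/C/G/T).
#' @param dict an [anchor_dict()].
#' @param graph a [build_graph()] object with the same k.
#' @param solid optional exact [solid_kmers()] set used as the solidity
#'   oracle; the compressor passes it so that a Bloom false positive can
#'   never be picked as a fresh anchor.  When `NULL`, graph membership
#'   is the oracle.
#' @return `list(index =, position =)` with a 0-based dictionary index
#'   and 0-based offset of the anchor in the read, or `NULL`.
#' @export
select_anchor <- function(read, dict, graph, solid = NULL) {
  .rb_select_anchor(read, dict$ptr, graph$ptr,
                    if (is.null(solid)) NULL else solid$ptr)
}

#' Encode a read as bifurcation events against the graph
#'
#' Walks right from the anchor (and symmetrically left, using
#' predecessor queries).  At each step, with S the graph successors of
#' the current node and c the read's next base: a unique successor
#' matching c emits nothing (simple path); a true bifurcation (c in S,
#' |S| >= 2) emits the nucleotide only; a divergence from the graph
#' (c not in S — a sequencing error or Bloom miss) emits nucleotide and
#' position.  The walk continues from the read's own kmer in all cases.
#'
#' @param read DNA string (A/C/G/T only; mask N first).
#' @param anchor_pos 0-based anchor offset in the read.
#' @param graph a [build_graph()] object.
#' @return list with `right` and `left` event tables (columns `type`:
#'   0 bifurcation / 1 positional, `nucleotide`, `position` 1-based or NA).
#' @export
encode_read <- function(read, anchor_pos, graph) {
  .rb_encode_read_events(read, as.integer(anchor_pos), graph$ptr)
}

#' Reconstruct a read from its anchor and bifurcation events
#'
#' Inverse of [encode_read()]: re-walks the graph from the anchor,
#' consuming positional events at their offsets and bifurcation events at
#' ambiguous nodes, out to `read_length` bases.
#'
#' @param anchor anchor kmer string (forward orientation).
#' @param anchor_pos 0-based anchor offset.
#' @param read_length total read length.
#' @param events list with `right`/`left` tables as from [encode_read()].
#' @param graph the identical graph used at encoding.
#' @return the reconstructed DNA string.
#' @export
decode_read <- function(anchor, anchor_pos, read_length, events, graph) {
  .rb_decode_read_events(anchor, as.integer(anchor_pos),
                         as.integer(read_length),
                         events$right, events$left, graph$ptr)
}
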
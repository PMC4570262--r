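#' Solid-kmer coverage threshold for quality smoothing
#'
#' A position may have its quality replaced by the cap character `'@'`
#' (Phred+33 score 31) when enough solid kmers cover it.  Writing
#' `delta = code('@') - code(q)` for the original quality character `q`,
#' the required coverage is `sigma = 2` when `delta <= 10` and
#' `delta - 5` otherwise: upgrading a low quality is riskier than
#' confirming a high one, so more evidence is demanded.  Qualities above
#' the cap (`delta < 0`) fall in the first branch.
#'
#' @param qual character vector of single Phred+33 quality characters
#'   (or a multi-character string, handled per character).
#' @return integer vector of sigma values.
#' @examples
#' qual_sigma("8")  # delta = 8  -> 2
#' qual_sigma("0")  # delta = 16 -> 11
#' @export
qual_sigma <- function(qual) {
  codes <- utf8ToInt(paste(qual, collapse = ""))
  delta <- utf8ToInt("@") - codes
  as.integer(ifelse(delta <= 10, 2L, delta - 5L))
}

#' Per-position solid kmer coverage of a read
#'
#' `coverage[i]` counts the kmer windows of the read that contain
#' position `i` and are present in the graph.  Interior positions of a
#' read lying on a simple path are covered by k windows; the terminal
#' bases by a single window.  Reads shorter than k have zero coverage
#' everywhere.  N characters are masked to 'A' before querying (their
#' windows are essentially never solid).
#'
#' @param read DNA string.
#' @param graph a [build_graph()] object.
#' @return integer vector, one count per base.
#' @export
solid_coverage <- function(read, graph) .rb_solid_coverage(read, graph$ptr)

#' Lossy quality smoothing backed by the de Bruijn graph
#'
#' Step 1 caps every quality above `'@'` at `'@'`.  Step 2 replaces the
#' quality at every position covered by at least `sigma(q)` solid kmers
#' (sigma computed from the *original* quality) by `'@'`; other positions
#' keep their capped value.  The transform is idempotent and never
#' lowers a quality below `min(original, '@')`.
#'
#' @param quals character vector of Phred+33 quality strings.
#' @param reads character vector of matching read sequences.
#' @param graph a [build_graph()] object.
#' @return character vector of smoothed quality strings.
#' @export
smooth_qualities <- function(quals, reads, graph) {
  .rb_smooth_block(quals, reads, graph$ptr)
}

# quality stream: newline-terminated concatenation, zlib (DEFLATE)
compress_quality_stream <- function(quals) {
  memCompress(charToRaw(paste0(paste(quals, collapse = "\n"), "\n")),
              type = "gzip")
}

decompress_quality_stream <- function(bytes, lengths) {
  txt <- rawToChar(memDecompress(bytes, type = "gzip"))
  quals <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(quals) != length(lengths) || any(nchar(quals) != lengths))
    stop("container corrupt: quality stream does not match read lengths")
  quals
}
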
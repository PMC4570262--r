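#' Count canonical kmers of a read set
#'
#' Builds an in-memory table of canonical-kmer occurrence counts.  Kmer
#' windows containing a non-ACGT character (for example N) are skipped.
#' The table is the input for the abundance histogram, the solidity
#' threshold inference and the solid-kmer set.
#'
#' @param reads character vector of read sequences; may be empty.
#' @param k kmer length (1 to 31); default 31.
#' @return an object of class `kmer_count_table`.
#' @seealso [kmer_histogram()], [solid_kmers()], [infer_solidity_threshold()]
#' @export
count_kmers <- function(reads, k = 31L) {
  .rb_state$count_calls <- .rb_state$count_calls + 1L
  tab <- structure(list(ptr = .rb_count_new(as.integer(k)), k = as.integer(k)),
                   class = "kmer_count_table")
  if (length(reads)) .rb_count_add(tab$ptr, reads)
  tab
}

# invocation counter: decompression must never trigger kmer counting
.rb_state <- new.env(parent = emptyenv())
.rb_state$count_calls <- 0L

#' @export
print.kmer_count_table <- function(x, ...) {
  st <- .rb_count_stats(x$ptr)
  cat(sprintf("kmer count table: k=%d, %.0f distinct canonical kmers, %.0f total\n",
              st$k, st$n_distinct, st$total))
  invisible(x)
}

# internal: add more reads to an existing table (streaming over blocks)
count_kmers_add <- function(tab, reads) {
  stopifnot(inherits(tab, "kmer_count_table"))
  if (length(reads)) .rb_count_add(tab$ptr, reads)
  invisible(tab)
}

#' Look up counts for specific kmers
#'
#' @param tab a [count_kmers()] table.
#' @param kmers character vector of kmers of length `k` (any strand; the
#'   canonical form is looked up).
#' @return numeric vector of counts (0 for absent kmers).
#' @export
kmer_count <- function(tab, kmers) {
  stopifnot(inherits(tab, "kmer_count_table"))
  .rb_count_get(tab$ptr, kmers)
}

#' Abundance histogram of a kmer count table
#'
#' @param tab a [count_kmers()] table.
#' @return data.frame with columns `abundance` (observed count values, in
#'   increasing order) and `n_kmers` (number of distinct canonical kmers
#'   with that count).
#' @export
kmer_histogram <- function(tab) {
  stopifnot(inherits(tab, "kmer_count_table"))
  h <- .rb_count_histogram(tab$ptr)
  data.frame(abundance = h$abundance, n_kmers = h$n_kmers)
}

#' Infer the kmer solidity threshold from an abundance histogram
#'
#' Sequencing errors produce a peak of low-abundance kmers well separated,
#' at sufficient coverage, from the genomic-coverage peak.  The threshold
#' is taken at the first local minimum between the two peaks: scanning the
#' observed abundances in increasing order, the first abundance whose
#' count drops below its predecessor's, does not exceed its successor's,
#' and is later followed by a larger count (the genomic peak).  The result
#' is clamped to `clamp`; a histogram with no such valley (unimodal, e.g.
#' very low coverage) falls back to `fallback`.
#'
#' @param hist a data.frame as returned by [kmer_histogram()].
#' @param clamp numeric length-2, allowed threshold range; default c(2, 20).
#' @param fallback threshold when the histogram is unimodal; default 3.
#' @return integer threshold `T_sol` (minimum abundance for a solid kmer).
#' @export
infer_solidity_threshold <- function(hist, clamp = c(2L, 20L), fallback = 3L) {
  if (is.null(hist) || nrow(hist) == 0L) stop("histogram is empty")
  a <- hist$abundance
  n <- hist$n_kmers
  m <- length(n)
  valley <- NA_integer_
  if (m >= 3L) {
    for (i in 2:(m - 1L)) {
      if (n[i] < n[i - 1L] && n[i] <= n[i + 1L] && max(n[(i + 1L):m]) > n[i]) {
        valley <- a[i]
        break
      }
    }
  }
  t_sol <- if (is.na(valley)) fallback else valley
  as.integer(min(max(t_sol, clamp[1L]), clamp[2L]))
}

#' Extract the solid kmer set
#'
#' Solid kmers are canonical kmers with dataset-wide count `>= t_sol`;
#' they are the nodes of the de Bruijn graph.  (The threshold is the
#' minimum solid abundance, i.e. the comparison is inclusive.)
#'
#' @param tab a [count_kmers()] table.
#' @param t_sol solidity threshold (>= 1).
#' @return an object of class `solid_kmer_set`.
#' @export
solid_kmers <- function(tab, t_sol) {
  stopifnot(inherits(tab, "kmer_count_table"))
  structure(list(ptr = .rb_solid_build(tab$ptr, as.integer(t_sol)), k = tab$k),
            class = "solid_kmer_set")
}

#' Build a solid set from explicit kmer strings (toy graphs, tests)
#'
#' @param kmers character vector of kmers (canonicalized, deduplicated).
#' @param k kmer length.
#' @return an object of class `solid_kmer_set`.
#' @export
solid_set <- function(kmers, k = nchar(kmers[1L])) {
  structure(list(ptr = .rb_solid_from_strings(kmers, as.integer(k)),
                 k = as.integer(k)), class = "solid_kmer_set")
}

#' @export
print.solid_kmer_set <- function(x, ...) {
  cat(sprintf("solid kmer set: k=%d, %.0f canonical kmers\n",
              x$k, .rb_solid_size(x$ptr)))
  invisible(x)
}

#' @rdname solid_kmers
#' @param solid a `solid_kmer_set`.
#' @export
solid_size <- function(solid) .rb_solid_size(solid$ptr)

#' @rdname solid_kmers
#' @param kmers character vector of kmers to test.
#' @export
solid_contains <- function(solid, kmers) .rb_solid_contains(solid$ptr, kmers)

#' @rdname solid_kmers
#' @export
solid_as_character <- function(solid) .rb_solid_as_strings(solid$ptr)
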
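#' Read a FASTQ or FASTA file
#'
#' Streams a well-formed 4-line-record FASTQ (Phred+33) or FASTA file
#' into parallel vectors, preserving read order byte-exactly.  The
#' format is auto-detected from the first character; gzip-compressed
#' input is handled transparently.  Wrapped FASTA sequence lines are
#' concatenated.  Headers are stored without the leading `@`/`>`.
#'
#' @param path input file (optionally .gz).
#' @return an object of class `read_set`: list with `header`,
#'   `sequence`, `quality` (NULL for FASTA) and `format`.
#' @export
read_fastx <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop("input file is empty: ", path)
  first <- substr(lines[1L], 1L, 1L)
  if (first == "@") {
    n <- length(lines)
    if (n %% 4L != 0L)
      stop("truncated FASTQ record at read ", n %/% 4L + 1L)
    hdr <- lines[seq.int(1L, n, 4L)]
    seqs <- lines[seq.int(2L, n, 4L)]
    plus <- lines[seq.int(3L, n, 4L)]
    qual <- lines[seq.int(4L, n, 4L)]
    bad <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad)) stop("malformed FASTQ header at read ", bad[1L])
    bad <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad)) stop("malformed FASTQ separator at read ", bad[1L])
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad))
      stop("sequence/quality length mismatch at read ", bad[1L])
    structure(list(header = substring(hdr, 2L), sequence = seqs,
                   quality = qual, format = "fastq"), class = "read_set")
  } else if (first == ">") {
    starts <- grep("^>", lines)
    ends <- c(starts[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(starts), function(i) {
      if (starts[i] == ends[i]) ""
      else paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
    }, character(1L))
    structure(list(header = substring(lines[starts], 2L), sequence = seqs,
                   quality = NULL, format = "fasta"), class = "read_set")
  } else {
    stop("unrecognized file format (expected '@' or '>'): ", path)
  }
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d %s records\n", length(x$sequence),
              toupper(x$format)))
  invisible(x)
}

#' Construct a read set in memory
#'
#' @param header,sequence,quality parallel character vectors; `quality`
#'   NULL for FASTA.
#' @return an object of class `read_set`.
#' @export
read_set <- function(header, sequence, quality = NULL) {
  stopifnot(length(header) == length(sequence),
            is.null(quality) || length(quality) == length(sequence))
  structure(list(header = header, sequence = sequence, quality = quality,
                 format = if (is.null(quality)) "fasta" else "fastq"),
            class = "read_set")
}

#' Write a read set to FASTQ/FASTA
#'
#' FASTQ records are written as 4 lines with a bare `+` separator; FASTA
#' sequences are written on a single line each (documented
#' normalization).
#'
#' @param records a `read_set`.
#' @param path output file.
#' @export
write_fastx <- function(records, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (records$format == "fastq") {
    txt <- paste0("@", records$header, "\n", records$sequence, "\n+\n",
                  records$quality)
  } else {
    txt <- paste0(">", records$header, "\n", records$sequence)
  }
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

# exact byte size of the normalized text form (used for compression ratios,
# independent of any gzip wrapping of the input)
fastx_bytes <- function(records) {
  n <- length(records$sequence)
  base <- sum(nchar(records$header, type = "bytes")) +
    sum(nchar(records$sequence, type = "bytes")) + n * 2L + n # @/> + 2 newlines
  if (records$format == "fastq")
    base + sum(nchar(records$quality, type = "bytes")) + n * 3L # +\n and qual \n
  else
    base
}
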
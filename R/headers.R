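#' Tokenize a read header
#'
#' Splits a header into maximal alphanumeric runs (fields) and single
#' non-alphanumeric separator characters (any character that is neither
#' a digit nor a letter).  Fields are classified `numeric` when they are
#' all digits without a leading zero (at most 18 digits); leading-zero
#' runs are classified `alpha` so the text round-trips exactly.
#' Re-joining the tokens reproduces the header byte-exactly.
#'
#' @param header a header string (without the leading `@`/`>`).
#' @return list with `text` and `kind` (`alpha`, `numeric`, `separator`).
#' @export
tokenize_header <- function(header) .rb_tokenize_header(header)

#' @rdname tokenize_header
#' @param tokens a list as returned by `tokenize_header()`.
#' @export
detokenize_header <- function(tokens) paste(tokens$text, collapse = "")

#' Delta-code a block of headers
#'
#' Each header is coded against the previous one, token by token:
#' `MATCH` when the token is unchanged, a zig-zag coded numerical
#' difference when both tokens are numeric and the difference is below
#' 2^15, and otherwise the longest-common-prefix length plus the new
#' suffix.  The first header is coded against an empty token list.  The
#' resulting op streams are entropy-coded into the container with one
#' order-0 model each.
#'
#' @param headers character vector of headers.
#' @return named list of integer symbol streams.
#' @export
encode_headers <- function(headers) .rb_encode_headers(headers)

#' @rdname encode_headers
#' @param streams list produced by `encode_headers()`.
#' @param n number of headers to decode.
#' @export
decode_headers <- function(streams, n) .rb_decode_headers(streams, as.numeric(n))
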
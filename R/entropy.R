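#' Adaptive order-0 arithmetic (range) coding
#'
#' A 32-bit range coder with byte renormalization, driven by an adaptive
#' order-0 frequency model: per-symbol counts start at 1, grow by 8 after
#' each coded symbol and are halved (floor 1) when the total exceeds
#' 2^16.  Encoder and decoder models evolve in lockstep, so
#' `arith_decode(arith_encode(s))` is the identity.  Each component
#' stream of the container uses its own model instance.
#'
#' @param symbols integer vector in `0:(alphabet_size - 1)`.
#' @param alphabet_size number of distinct symbols (1 to 32768).
#' @return `arith_encode()`: raw vector (5 bytes for an empty input).
#' @examples
#' x <- sample(0:3, 1000, replace = TRUE)
#' identical(arith_decode(arith_encode(x, 4), length(x), 4), x)
#' @export
arith_encode <- function(symbols, alphabet_size) {
  .rb_arith_encode(as.integer(symbols), as.integer(alphabet_size))
}

#' @rdname arith_encode
#' @param data raw vector produced by `arith_encode()`.
#' @param n number of symbols to decode.
#' @export
arith_decode <- function(data, n, alphabet_size) {
  .rb_arith_decode(data, as.numeric(n), as.integer(alphabet_size))
}
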
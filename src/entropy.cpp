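#include <Rcpp.h>
#include "rangecoder.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".rb_arith_encode")]]
RawVector rb_arith_encode(IntegerVector symbols, int nsym) {
    if (nsym < 1 || nsym > 1 << 15) stop("alphabet size out of range");
    rb::RangeEncoder enc;
    rb::FreqModel model(nsym);
    for (R_xlen_t i = 0; i < symbols.size(); ++i) {
        int s = symbols[i];
        if (s < 0 || s >= nsym) stop("symbol %d outside alphabet of size %d", s, nsym);
        model.encode_symbol(enc, s);
    }
    enc.flush();
    RawVector out(enc.out.size());
    std::copy(enc.out.begin(), enc.out.end(), out.begin());
    return out;
}

// [[Rcpp::export(name = ".rb_arith_decode")]]
IntegerVector rb_arith_decode(RawVector data, double n, int nsym) {
    if (nsym < 1 || nsym > 1 << 15) stop("alphabet size out of range");
    R_xlen_t nn = R_xlen_t(n);
    IntegerVector out(nn);
    if (nn == 0) return out;
    rb::RangeDecoder dec(RAW(data), size_t(data.size()));
    rb::FreqModel model(nsym);
    for (R_xlen_t i = 0; i < nn; ++i) out[i] = model.decode_symbol(dec);
    return out;
}
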
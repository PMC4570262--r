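#include <Rcpp.h>
#include "kmer_core.h"
using namespace Rcpp;

// String-level kmer operations exposed to R.  Values are returned as doubles
// (exact for k <= 26; the packed integer is an implementation detail, the
// string form is the API of record).

// [[Rcpp::export(name = ".rb_kmer_encode")]]
NumericVector rb_kmer_encode(CharacterVector seqs) {
    NumericVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        int k = int(strlen(s));
        if (k < 1 || k > rb::KMAX) stop("kmer length must be in 1..%d", rb::KMAX);
        if (k > 26) stop("numeric kmer codes are only exact for k <= 26");
        out[i] = double(rb::encode_kmer(s, k));
    }
    return out;
}

// [[Rcpp::export(name = ".rb_kmer_decode")]]
CharacterVector rb_kmer_decode(NumericVector values, int k) {
    if (k < 1 || k > 26) stop("k must be in 1..26 for numeric codes");
    CharacterVector out(values.size());
    for (R_xlen_t i = 0; i < values.size(); ++i)
        out[i] = rb::decode_kmer(uint64_t(values[i]), k);
    return out;
}

// [[Rcpp::export(name = ".rb_kmer_revcomp")]]
CharacterVector rb_kmer_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        int k = int(strlen(s));
        if (k < 1 || k > rb::KMAX) stop("kmer length must be in 1..%d", rb::KMAX);
        out[i] = rb::decode_kmer(rb::revcomp_kmer(rb::encode_kmer(s, k), k), k);
    }
    return out;
}

// [[Rcpp::export(name = ".rb_kmer_canonical")]]
CharacterVector rb_kmer_canonical(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        int k = int(strlen(s));
        if (k < 1 || k > rb::KMAX) stop("kmer length must be in 1..%d", rb::KMAX);
        out[i] = rb::decode_kmer(rb::canonical_kmer(rb::encode_kmer(s, k), k), k);
    }
    return out;
}

// [[Rcpp::export(name = ".rb_kmerize")]]
CharacterVector rb_kmerize(std::string seq, int k) {
    if (k < 1 || k > rb::KMAX) stop("k must be in 1..%d", rb::KMAX);
    int l = int(seq.size());
    if (l < k) return CharacterVector(0);
    CharacterVector out(l - k + 1);
    for (int i = 0; i + k <= l; ++i) out[i] = seq.substr(i, k);
    return out;
}

// [[Rcpp::export(name = ".rb_kmer_successors")]]
CharacterVector rb_kmer_successors(std::string seq) {
    int k = int(seq.size());
    if (k < 1 || k > rb::KMAX) stop("kmer length must be in 1..%d", rb::KMAX);
    uint64_t v = rb::encode_kmer(seq.c_str(), k);
    CharacterVector out(4);
    for (int b = 0; b < 4; ++b)
        out[b] = rb::decode_kmer(rb::next_kmer(v, b, k), k);
    return out;
}

// [[Rcpp::export(name = ".rb_kmer_predecessors")]]
CharacterVector rb_kmer_predecessors(std::string seq) {
    int k = int(seq.size());
    if (k < 1 || k > rb::KMAX) stop("kmer length must be in 1..%d", rb::KMAX);
    uint64_t v = rb::encode_kmer(seq.c_str(), k);
    CharacterVector out(4);
    for (int b = 0; b < 4; ++b)
        out[b] = rb::decode_kmer(rb::prev_kmer(v, b, k), k);
    return out;
}
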
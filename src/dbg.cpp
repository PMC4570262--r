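#include <Rcpp.h>
#include "bloom_core.h"
#include "structs.h"
using namespace Rcpp;
using rb::Bloom;
using rb::SolidSet;

// default hash seeds; always written into the container so files remain
// decodable if the defaults ever change
static const uint64_t SEED1 = 0x9E3779B97F4A7C15ULL;
static const uint64_t SEED2 = 0xC2B2AE3D27D4EB4FULL;

static RawVector u64_to_raw(uint64_t v) {
    RawVector r(8);
    for (int i = 0; i < 8; ++i) r[i] = (v >> (8 * i)) & 0xFF;
    return r;
}

static uint64_t raw_to_u64(RawVector r) {
    if (r.size() != 8) stop("expected 8 raw bytes");
    uint64_t v = 0;
    for (int i = 7; i >= 0; --i) v = (v << 8) | uint64_t(r[i]);
    return v;
}

// [[Rcpp::export(name = ".rb_bloom_build")]]
SEXP rb_bloom_build(SEXP solid, double bits_per_kmer) {
    XPtr<SolidSet> s(solid);
    if (s->v.empty())
        stop("solid kmer set is empty; lower the abundance threshold (T_sol)");
    if (bits_per_kmer < 1) stop("bits_per_kmer must be >= 1");
    uint64_t m = uint64_t(std::ceil(bits_per_kmer * double(s->v.size())));
    m = ((m + 7) / 8) * 8; // round up to a byte multiple
    int h = Bloom::hashes_for_bits(bits_per_kmer);
    Bloom* g = new Bloom(m, h, SEED1, SEED2, s->k);
    for (uint64_t v : s->v) g->insert(v);
    return XPtr<Bloom>(g, true);
}

// [[Rcpp::export(name = ".rb_bloom_empty")]]
SEXP rb_bloom_empty(double m_bits, int h, int k) {
    Bloom* g = new Bloom(uint64_t(m_bits), h, SEED1, SEED2, k);
    return XPtr<Bloom>(g, true);
}

// [[Rcpp::export(name = ".rb_bloom_insert")]]
void rb_bloom_insert(SEXP graph, CharacterVector kmers) {
    XPtr<Bloom> g(graph);
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        if (int(strlen(s)) != g->k) stop("kmer length mismatch");
        g->insert(rb::encode_kmer(s, g->k));
    }
}

// [[Rcpp::export(name = ".rb_bloom_contains")]]
LogicalVector rb_bloom_contains(SEXP graph, CharacterVector kmers) {
    XPtr<Bloom> g(graph);
    LogicalVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        if (int(strlen(s)) != g->k) stop("kmer length mismatch");
        out[i] = g->contains(rb::encode_kmer(s, g->k));
    }
    return out;
}

// [[Rcpp::export(name = ".rb_bloom_successors")]]
CharacterVector rb_bloom_successors(SEXP graph, std::string kmer) {
    XPtr<Bloom> g(graph);
    if (int(kmer.size()) != g->k) stop("kmer length mismatch");
    uint64_t v = rb::encode_kmer(kmer.c_str(), g->k);
    int m = g->successor_mask(v);
    std::vector<std::string> out;
    for (int b = 0; b < 4; ++b)
        if (m & (1 << b))
            out.push_back(rb::decode_kmer(rb::next_kmer(v, b, g->k), g->k));
    return wrap(out);
}

// [[Rcpp::export(name = ".rb_bloom_params")]]
List rb_bloom_params(SEXP graph) {
    XPtr<Bloom> g(graph);
    return List::create(_["m_bits"] = double(g->m_bits), _["h"] = g->h,
                        _["k"] = g->k, _["n_inserted"] = double(g->n_inserted),
                        _["seed1"] = u64_to_raw(g->seed1),
                        _["seed2"] = u64_to_raw(g->seed2));
}

// [[Rcpp::export(name = ".rb_bloom_bits")]]
RawVector rb_bloom_bits(SEXP graph) {
    XPtr<Bloom> g(graph);
    RawVector out(g->bits.size());
    std::copy(g->bits.begin(), g->bits.end(), out.begin());
    return out;
}

// [[Rcpp::export(name = ".rb_bloom_from_parts")]]
SEXP rb_bloom_from_parts(double m_bits, int h, int k, double n_inserted,
                         RawVector seed1, RawVector seed2, RawVector bits) {
    Bloom* g = new Bloom(uint64_t(m_bits), h, raw_to_u64(seed1),
                         raw_to_u64(seed2), k);
    if (size_t(bits.size()) != g->bits.size())
        stop("bit-array length does not match m");
    std::copy(bits.begin(), bits.end(), g->bits.begin());
    g->n_inserted = uint64_t(n_inserted);
    return XPtr<Bloom>(g, true);
}
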
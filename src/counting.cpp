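#include <Rcpp.h>
#include "kmer_core.h"
#include "structs.h"
using namespace Rcpp;
using rb::CountTable;
using rb::SolidSet;

// In-memory canonical kmer counting.  Replaces the disk-based streaming
// counters used by assembly toolkits; fine up to ~1e8 distinct kmers.

// [[Rcpp::export(name = ".rb_count_new")]]
SEXP rb_count_new(int k) {
    if (k < 1 || k > rb::KMAX) stop("k must be in 1..%d", rb::KMAX);
    CountTable* t = new CountTable();
    t->k = k;
    return XPtr<CountTable>(t, true);
}

// Rolling 2-bit scan; windows containing a non-ACGT base are skipped.
static void count_seq(CountTable& t, const char* s, int l) {
    const int k = t.k;
    const uint64_t mask = rb::kmer_mask(k);
    uint64_t v = 0;
    int run = 0;
    for (int i = 0; i < l; ++i) {
        int b = rb::base_code(s[i]);
        if (b < 0) { run = 0; v = 0; continue; }
        v = ((v << 2) | uint64_t(b)) & mask;
        if (++run >= k) t.m[rb::canonical_kmer(v, k)]++;
    }
}

// [[Rcpp::export(name = ".rb_count_add")]]
void rb_count_add(SEXP tab, CharacterVector reads) {
    XPtr<CountTable> t(tab);
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        const char* s = CHAR(STRING_ELT(reads, i));
        count_seq(*t, s, int(strlen(s)));
    }
}

// [[Rcpp::export(name = ".rb_count_stats")]]
List rb_count_stats(SEXP tab) {
    XPtr<CountTable> t(tab);
    double total = 0;
    for (const auto& kv : t->m) total += kv.second;
    return List::create(_["k"] = t->k,
                        _["n_distinct"] = double(t->m.size()),
                        _["total"] = total);
}

// [[Rcpp::export(name = ".rb_count_histogram")]]
List rb_count_histogram(SEXP tab) {
    XPtr<CountTable> t(tab);
    std::unordered_map<uint32_t, double> h;
    for (const auto& kv : t->m) h[kv.second] += 1;
    std::vector<uint32_t> ab;
    ab.reserve(h.size());
    for (const auto& kv : h) ab.push_back(kv.first);
    std::sort(ab.begin(), ab.end());
    IntegerVector a(ab.size());
    NumericVector n(ab.size());
    for (size_t i = 0; i < ab.size(); ++i) { a[i] = int(ab[i]); n[i] = h[ab[i]]; }
    return List::create(_["abundance"] = a, _["n_kmers"] = n);
}

// [[Rcpp::export(name = ".rb_count_get")]]
NumericVector rb_count_get(SEXP tab, CharacterVector kmers) {
    XPtr<CountTable> t(tab);
    NumericVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        if (int(strlen(s)) != t->k) stop("kmer length mismatch");
        uint64_t c = rb::canonical_kmer(rb::encode_kmer(s, t->k), t->k);
        auto it = t->m.find(c);
        out[i] = (it == t->m.end()) ? 0 : double(it->second);
    }
    return out;
}

// [[Rcpp::export(name = ".rb_solid_build")]]
SEXP rb_solid_build(SEXP tab, int t_sol) {
    XPtr<CountTable> t(tab);
    if (t_sol < 1) stop("t_sol must be >= 1");
    SolidSet* s = new SolidSet();
    s->k = t->k;
    for (const auto& kv : t->m)
        if (int(kv.second) >= t_sol) s->v.push_back(kv.first);
    std::sort(s->v.begin(), s->v.end());
    return XPtr<SolidSet>(s, true);
}

// [[Rcpp::export(name = ".rb_solid_size")]]
double rb_solid_size(SEXP solid) {
    XPtr<SolidSet> s(solid);
    return double(s->v.size());
}

// [[Rcpp::export(name = ".rb_solid_k")]]
int rb_solid_k(SEXP solid) {
    XPtr<SolidSet> s(solid);
    return s->k;
}

// [[Rcpp::export(name = ".rb_solid_contains")]]
LogicalVector rb_solid_contains(SEXP solid, CharacterVector kmers) {
    XPtr<SolidSet> s(solid);
    LogicalVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* q = CHAR(STRING_ELT(kmers, i));
        if (int(strlen(q)) != s->k) stop("kmer length mismatch");
        out[i] = s->contains(rb::canonical_kmer(rb::encode_kmer(q, s->k), s->k));
    }
    return out;
}

// [[Rcpp::export(name = ".rb_solid_as_strings")]]
CharacterVector rb_solid_as_strings(SEXP solid) {
    XPtr<SolidSet> s(solid);
    if (s->v.size() > 5000000) stop("solid set too large to materialize");
    CharacterVector out(s->v.size());
    for (size_t i = 0; i < s->v.size(); ++i)
        out[i] = rb::decode_kmer(s->v[i], s->k);
    return out;
}

// Build a solid set directly from explicit kmer strings (tests, toy graphs).
// [[Rcpp::export(name = ".rb_solid_from_strings")]]
SEXP rb_solid_from_strings(CharacterVector kmers, int k) {
    if (k < 1 || k > rb::KMAX) stop("k must be in 1..%d", rb::KMAX);
    SolidSet* s = new SolidSet();
    s->k = k;
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* q = CHAR(STRING_ELT(kmers, i));
        if (int(strlen(q)) != k) stop("kmer length mismatch");
        s->v.push_back(rb::canonical_kmer(rb::encode_kmer(q, k), k));
    }
    std::sort(s->v.begin(), s->v.end());
    s->v.erase(std::unique(s->v.begin(), s->v.end()), s->v.end());
    return XPtr<SolidSet>(s, true);
}
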
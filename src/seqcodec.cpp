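#include <Rcpp.h>
#include <deque>
#include "bloom_core.h"
#include "structs.h"
using namespace Rcpp;
using rb::Bloom;
using rb::AnchorDict;

// ---------------------------------------------------------------------------
// Per-read path encoding against the probabilistic de Bruijn graph.
//
// Walking right from the anchor, with S = graph successors of the current
// node and c = the read's next base:
//   (a) |S| == 1 and c in S : simple path, nothing emitted;
//   (b) c in S, |S| >= 2    : true bifurcation, emit (c) without position;
//   (c) c not in S          : divergence from the graph (sequencing error or
//                             Bloom miss), emit (c, position).
// After (a)/(b) the walk continues from the read's own kmer (which is a
// graph node).  After (c) it resynchronizes with the graph: it continues
// from the smallest graph successor (the genomic path, up to Bloom false
// positives), so an isolated substitution costs exactly one positional
// event instead of cascading over the next k-1 windows.  Only at a dead
// end (|S| = 0) does it fall back to the read's own kmer.  The left side
// is the mirror image using predecessor queries.  Decoding replays the
// same walk with the same state rule: positional events override the graph
// at their offset, non-positional events resolve bifurcations, simple
// paths need no symbols.
// ---------------------------------------------------------------------------

static const int EV_BRANCH = 0;
static const int EV_ERROR  = 1;

struct Event { int type; int nt; int pos; };

// escaped byte value: 0..254 direct, 255 then LEB128 of the full value
static void esc_push(std::vector<int>& v, long long x) {
    if (x < 255) { v.push_back(int(x)); return; }
    v.push_back(255);
    unsigned long long u = (unsigned long long)x;
    while (u >= 128) { v.push_back(int((u & 127) | 128)); u >>= 7; }
    v.push_back(int(u));
}

static long long esc_get(const int* v, R_xlen_t n, R_xlen_t& i) {
    if (i >= n) stop("container corrupt: stream exhausted");
    int b = v[i++];
    if (b < 255) return b;
    unsigned long long u = 0;
    int shift = 0;
    for (;;) {
        if (i >= n) stop("container corrupt: stream exhausted");
        int c = v[i++];
        u |= (unsigned long long)(c & 127) << shift;
        if (!(c & 128)) break;
        shift += 7;
    }
    return (long long)u;
}

// plain LEB128 (used for anchor indices, always self-delimiting)
static void varint_push(std::vector<int>& v, unsigned long long u) {
    while (u >= 128) { v.push_back(int((u & 127) | 128)); u >>= 7; }
    v.push_back(int(u));
}

static unsigned long long varint_get(const int* v, R_xlen_t n, R_xlen_t& i) {
    unsigned long long u = 0;
    int shift = 0;
    for (;;) {
        if (i >= n) stop("container corrupt: stream exhausted");
        int c = v[i++];
        u |= (unsigned long long)(c & 127) << shift;
        if (!(c & 128)) break;
        shift += 7;
    }
    return u;
}

// shared state rule: base used to extend the walk after reading base c
// against successor mask S
static inline int continuation_base(int S, int c) {
    if ((S >> c) & 1) return c;                       // read base is in graph
    if (S) return __builtin_ctz(unsigned(S));         // resync: smallest edge
    return c;                                         // dead end: read base
}

// right walk over masked read s[apos+k .. l-1], appending events
static void walk_right(const std::string& s, int apos, const Bloom& g,
                       std::vector<Event>& ev) {
    const int k = g.k, l = int(s.size());
    uint64_t cur = rb::encode_kmer(s.c_str() + apos, k);
    for (int i = apos + k; i < l; ++i) {
        int c = rb::base_code(s[i]);
        int S = g.successor_mask(cur);
        bool in_graph = (S >> c) & 1;
        int npop = __builtin_popcount(unsigned(S));
        if (in_graph && npop >= 2)
            ev.push_back({EV_BRANCH, c, -1});
        else if (!in_graph)
            ev.push_back({EV_ERROR, c, i});
        cur = rb::next_kmer(cur, continuation_base(S, c), k);
    }
}

static void walk_left(const std::string& s, int apos, const Bloom& g,
                      std::vector<Event>& ev) {
    const int k = g.k;
    uint64_t cur = rb::encode_kmer(s.c_str() + apos, k);
    for (int i = apos - 1; i >= 0; --i) {
        int c = rb::base_code(s[i]);
        int P = g.predecessor_mask(cur);
        bool in_graph = (P >> c) & 1;
        int npop = __builtin_popcount(unsigned(P));
        if (in_graph && npop >= 2)
            ev.push_back({EV_BRANCH, c, -1});
        else if (!in_graph)
            ev.push_back({EV_ERROR, c, i});
        cur = rb::prev_kmer(cur, continuation_base(P, c), k);
    }
}

// decoding: replay one direction, consuming events from a queue
static void replay_right(std::string& s, int apos, int l, const Bloom& g,
                         std::deque<Event>& ev) {
    const int k = g.k;
    uint64_t cur = rb::encode_kmer(s.c_str() + apos, k);
    for (int i = apos + k; i < l; ++i) {
        int S = g.successor_mask(cur);
        int c;
        if (!ev.empty() && ev.front().type == EV_ERROR && ev.front().pos == i) {
            c = ev.front().nt; ev.pop_front();
        } else {
            int npop = __builtin_popcount(unsigned(S));
            if (npop == 1) {
                c = __builtin_ctz(unsigned(S));
            } else if (npop >= 2) {
                if (ev.empty() || ev.front().type != EV_BRANCH)
                    stop("container corrupt: bifurcation list exhausted");
                c = ev.front().nt; ev.pop_front();
            } else {
                stop("container corrupt: dead end without positional event");
            }
        }
        s[i] = rb::code_base(c);
        cur = rb::next_kmer(cur, continuation_base(S, c), k);
    }
}

static void replay_left(std::string& s, int apos, const Bloom& g,
                        std::deque<Event>& ev) {
    const int k = g.k;
    uint64_t cur = rb::encode_kmer(s.c_str() + apos, k);
    for (int i = apos - 1; i >= 0; --i) {
        int P = g.predecessor_mask(cur);
        int c;
        if (!ev.empty() && ev.front().type == EV_ERROR && ev.front().pos == i) {
            c = ev.front().nt; ev.pop_front();
        } else {
            int npop = __builtin_popcount(unsigned(P));
            if (npop == 1) {
                c = __builtin_ctz(unsigned(P));
            } else if (npop >= 2) {
                if (ev.empty() || ev.front().type != EV_BRANCH)
                    stop("container corrupt: bifurcation list exhausted");
                c = ev.front().nt; ev.pop_front();
            } else {
                stop("container corrupt: dead end without positional event");
            }
        }
        s[i] = rb::code_base(c);
        cur = rb::prev_kmer(cur, continuation_base(P, c), k);
    }
}

// ---------------------------------------------------------------------------
// Anchor dictionary
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".rb_dict_new")]]
SEXP rb_dict_new(int k) {
    if (k < 1 || k > rb::KMAX) stop("k must be in 1..%d", rb::KMAX);
    AnchorDict* d = new AnchorDict();
    d->k = k;
    return XPtr<AnchorDict>(d, true);
}

// [[Rcpp::export(name = ".rb_dict_size")]]
double rb_dict_size(SEXP dict) {
    XPtr<AnchorDict> d(dict);
    return double(d->entries.size());
}

// [[Rcpp::export(name = ".rb_dict_get")]]
CharacterVector rb_dict_get(SEXP dict, NumericVector idx) {
    XPtr<AnchorDict> d(dict);
    CharacterVector out(idx.size());
    for (R_xlen_t i = 0; i < idx.size(); ++i) {
        long long j = (long long)idx[i];
        if (j < 0 || j >= (long long)d->entries.size()) stop("anchor index out of range");
        out[i] = rb::decode_kmer(d->entries[size_t(j)], d->k);
    }
    return out;
}

// [[Rcpp::export(name = ".rb_dict_find")]]
double rb_dict_find(SEXP dict, std::string kmer) {
    XPtr<AnchorDict> d(dict);
    if (int(kmer.size()) != d->k) stop("kmer length mismatch");
    return double(d->find(rb::encode_kmer(kmer.c_str(), d->k)));
}

// [[Rcpp::export(name = ".rb_dict_add")]]
double rb_dict_add(SEXP dict, std::string kmer) {
    XPtr<AnchorDict> d(dict);
    if (int(kmer.size()) != d->k) stop("kmer length mismatch");
    uint64_t v = rb::encode_kmer(kmer.c_str(), d->k);
    long long i = d->find(v);
    if (i >= 0) return double(i);
    return double(d->add(v));
}

// dictionary as one base-symbol stream (alphabet 4) for serialization
// [[Rcpp::export(name = ".rb_dict_symbols")]]
IntegerVector rb_dict_symbols(SEXP dict) {
    XPtr<AnchorDict> d(dict);
    IntegerVector out(d->entries.size() * size_t(d->k));
    R_xlen_t p = 0;
    for (uint64_t v : d->entries)
        for (int i = d->k - 1; i >= 0; --i)
            out[p++] = int((v >> (2 * i)) & 3);
    return out;
}

// [[Rcpp::export(name = ".rb_dict_from_symbols")]]
SEXP rb_dict_from_symbols(IntegerVector symbols, int k) {
    if (k < 1 || k > rb::KMAX) stop("k must be in 1..%d", rb::KMAX);
    if (symbols.size() % k != 0) stop("container corrupt: dictionary stream length");
    AnchorDict* d = new AnchorDict();
    d->k = k;
    for (R_xlen_t i = 0; i < symbols.size(); i += k) {
        uint64_t v = 0;
        for (int j = 0; j < k; ++j) v = (v << 2) | uint64_t(symbols[i + j] & 3);
        d->add(v);
    }
    return XPtr<AnchorDict>(d, true);
}

// ---------------------------------------------------------------------------
// Anchor selection: first dictionary hit scanning left to right, else the
// leftmost solid kmer, which is appended to the dictionary, else none (read
// goes raw).  The solidity oracle is the exact solid set when available
// (compression has it; Bloom false positives would otherwise occasionally
// anchor a read on an error kmer and cascade positional events), falling
// back to graph membership.
// ---------------------------------------------------------------------------

struct SolidOracle {
    const Bloom* bloom;
    const rb::SolidSet* exact; // preferred when non-null
    int k;
    bool contains(uint64_t v) const {
        uint64_t c = rb::canonical_kmer(v, k);
        return exact ? exact->contains(c) : bloom->contains(c);
    }
};

static long long select_anchor_impl(const std::string& s, AnchorDict& d,
                                    const SolidOracle& oracle, int& pos_out) {
    const int k = oracle.k, l = int(s.size());
    if (l < k) return -1;
    uint64_t v = rb::encode_kmer(s.c_str(), k);
    long long first_solid_pos = -1;
    uint64_t first_solid_kmer = 0;
    for (int i = 0;; ++i) {
        long long idx = d.find(v);
        if (idx >= 0) { pos_out = i; return idx; }
        if (first_solid_pos < 0 && oracle.contains(v)) {
            first_solid_pos = i;
            first_solid_kmer = v;
        }
        if (i + k >= l) break;
        v = rb::next_kmer(v, rb::base_code(s[i + k]), k);
    }
    if (first_solid_pos >= 0) {
        pos_out = int(first_solid_pos);
        return (long long)d.add(first_solid_kmer);
    }
    return -1;
}

static SolidOracle make_oracle(const Bloom* g, SEXP solid) {
    SolidOracle o;
    o.bloom = g;
    o.exact = nullptr;
    o.k = g->k;
    if (!Rf_isNull(solid)) {
        XPtr<rb::SolidSet> s(solid);
        if (s->k != g->k) stop("solid set and graph disagree on k");
        o.exact = s.get();
    }
    return o;
}

// [[Rcpp::export(name = ".rb_select_anchor")]]
SEXP rb_select_anchor(std::string read, SEXP dict, SEXP graph,
                      SEXP solid = R_NilValue) {
    XPtr<AnchorDict> d(dict);
    XPtr<Bloom> g(graph);
    if (d->k != g->k) stop("dictionary and graph disagree on k");
    SolidOracle oracle = make_oracle(g.get(), solid);
    int pos = 0;
    long long idx = select_anchor_impl(read, *d, oracle, pos);
    if (idx < 0) return R_NilValue;
    return List::create(_["index"] = double(idx), _["position"] = pos);
}

// ---------------------------------------------------------------------------
// Single-read encode/decode (inspection & tests; the block codec below is
// the production path)
// ---------------------------------------------------------------------------

static List events_to_list(const std::vector<Event>& ev) {
    int n = int(ev.size());
    CharacterVector nt(n);
    IntegerVector type(n), pos(n);
    for (int i = 0; i < n; ++i) {
        type[i] = ev[i].type;
        nt[i] = std::string(1, rb::code_base(ev[i].nt));
        pos[i] = ev[i].type == EV_ERROR ? ev[i].pos + 1 : NA_INTEGER; // 1-based
    }
    return List::create(_["type"] = type, _["nucleotide"] = nt, _["position"] = pos);
}

// [[Rcpp::export(name = ".rb_encode_read_events")]]
List rb_encode_read_events(std::string read, int anchor_pos, SEXP graph) {
    XPtr<Bloom> g(graph);
    const int k = g->k, l = int(read.size());
    if (anchor_pos < 0 || anchor_pos + k > l) stop("anchor position out of range");
    std::vector<Event> right, left;
    walk_right(read, anchor_pos, *g, right);
    walk_left(read, anchor_pos, *g, left);
    return List::create(_["right"] = events_to_list(right),
                        _["left"] = events_to_list(left));
}

static std::deque<Event> list_to_events(List lst) {
    IntegerVector type = lst["type"], pos = lst["position"];
    CharacterVector nt = lst["nucleotide"];
    std::deque<Event> ev;
    for (R_xlen_t i = 0; i < type.size(); ++i) {
        int p = (pos[i] == NA_INTEGER) ? -1 : pos[i] - 1;
        ev.push_back({type[i], rb::base_code(CHAR(STRING_ELT(nt, i))[0]), p});
    }
    return ev;
}

// [[Rcpp::export(name = ".rb_decode_read_events")]]
std::string rb_decode_read_events(std::string anchor, int anchor_pos,
                                  int read_length, List right, List left,
                                  SEXP graph) {
    XPtr<Bloom> g(graph);
    const int k = g->k;
    if (int(anchor.size()) != k) stop("anchor length mismatch");
    if (anchor_pos < 0 || anchor_pos + k > read_length)
        stop("anchor position out of range");
    std::string s(read_length, 'A');
    for (int i = 0; i < k; ++i) s[anchor_pos + i] = anchor[i];
    std::deque<Event> evr = list_to_events(right), evl = list_to_events(left);
    replay_right(s, anchor_pos, read_length, *g, evr);
    replay_left(s, anchor_pos, *g, evl);
    if (!evr.empty() || !evl.empty())
        stop("container corrupt: unconsumed bifurcation events");
    return s;
}

// ---------------------------------------------------------------------------
// Block codec: component symbol streams for a block of reads
// ---------------------------------------------------------------------------

struct BlockStreams {
    std::vector<int> mode, len, aidx, apos, nbr, nbl, btype, bnt, bpos,
        nn, npos, raw;
};

static void push_events(BlockStreams& b, const std::vector<Event>& ev) {
    for (const Event& e : ev) {
        b.btype.push_back(e.type);
        b.bnt.push_back(e.nt);
        if (e.type == EV_ERROR) esc_push(b.bpos, e.pos);
    }
}

// [[Rcpp::export(name = ".rb_encode_block")]]
List rb_encode_block(CharacterVector seqs, SEXP dict, SEXP graph,
                     SEXP solid = R_NilValue) {
    XPtr<AnchorDict> d(dict);
    XPtr<Bloom> g(graph);
    if (d->k != g->k) stop("dictionary and graph disagree on k");
    const int k = g->k;
    SolidOracle oracle = make_oracle(g.get(), solid);
    BlockStreams b;
    int n_raw = 0;

    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
        const char* cs = CHAR(STRING_ELT(seqs, r));
        int l = int(strlen(cs));
        std::string s(cs, size_t(l));
        std::vector<int> npositions;
        for (int i = 0; i < l; ++i) {
            char c = s[i];
            if (c == 'N' || c == 'n') { npositions.push_back(i); s[i] = 'A'; }
            else if (rb::base_code(c) < 0)
                stop("read %lld: invalid base '%c' (only A,C,G,T,N supported)",
                     (long long)r + 1, c);
        }

        int apos = 0;
        long long aidx = (l >= k) ? select_anchor_impl(s, *d, oracle, apos) : -1;

        if (aidx < 0) { // raw mode: original bases verbatim, N included
            ++n_raw;
            b.mode.push_back(1);
            esc_push(b.len, l);
            for (int i = 0; i < l; ++i) {
                char c = cs[i];
                int v = (c == 'N' || c == 'n') ? 4 : rb::base_code(c);
                b.raw.push_back(v);
            }
            continue;
        }

        b.mode.push_back(0);
        esc_push(b.len, l);
        varint_push(b.aidx, (unsigned long long)aidx);
        esc_push(b.apos, apos);

        std::vector<Event> right, left;
        walk_right(s, apos, *g, right);
        walk_left(s, apos, *g, left);
        esc_push(b.nbr, (long long)right.size());
        esc_push(b.nbl, (long long)left.size());
        push_events(b, right);
        push_events(b, left);

        esc_push(b.nn, (long long)npositions.size());
        int prev = 0;
        for (size_t j = 0; j < npositions.size(); ++j) {
            esc_push(b.npos, npositions[j] - prev);
            prev = npositions[j];
        }
    }

    return List::create(
        _["mode"] = wrap(b.mode), _["len"] = wrap(b.len),
        _["aidx"] = wrap(b.aidx), _["apos"] = wrap(b.apos),
        _["nbr"] = wrap(b.nbr), _["nbl"] = wrap(b.nbl),
        _["btype"] = wrap(b.btype), _["bnt"] = wrap(b.bnt),
        _["bpos"] = wrap(b.bpos), _["nn"] = wrap(b.nn),
        _["npos"] = wrap(b.npos), _["raw"] = wrap(b.raw),
        _["n_raw"] = n_raw);
}

// [[Rcpp::export(name = ".rb_decode_block")]]
CharacterVector rb_decode_block(List streams, double n_reads, SEXP dict,
                                SEXP graph) {
    XPtr<AnchorDict> d(dict);
    XPtr<Bloom> g(graph);
    const int k = g->k;
    IntegerVector mode = streams["mode"], len = streams["len"],
        aidx = streams["aidx"], apos = streams["apos"], nbr = streams["nbr"],
        nbl = streams["nbl"], btype = streams["btype"], bnt = streams["bnt"],
        bpos = streams["bpos"], nn = streams["nn"], npos = streams["npos"],
        raw = streams["raw"];
    R_xlen_t im = 0, il = 0, ia = 0, ip = 0, inr = 0, inl = 0, ibt = 0,
        ibn = 0, ibp = 0, inn = 0, inp = 0, irw = 0;
    R_xlen_t n = R_xlen_t(n_reads);
    CharacterVector out(n);

    for (R_xlen_t r = 0; r < n; ++r) {
        if (im >= mode.size()) stop("container corrupt: mode stream exhausted");
        int md = mode[im++];
        long long l = esc_get(INTEGER(len), len.size(), il);

        if (md == 1) {
            std::string s(size_t(l), 'N');
            for (long long i = 0; i < l; ++i) {
                if (irw >= raw.size()) stop("container corrupt: raw stream exhausted");
                int v = raw[irw++];
                s[size_t(i)] = (v == 4) ? 'N' : rb::code_base(v);
            }
            out[r] = s;
            continue;
        }

        unsigned long long ai = varint_get(INTEGER(aidx), aidx.size(), ia);
        long long ap = esc_get(INTEGER(apos), apos.size(), ip);
        if (ai >= d->entries.size()) stop("container corrupt: anchor index out of range");
        if (ap < 0 || ap + k > l) stop("container corrupt: anchor position");

        long long enr = esc_get(INTEGER(nbr), nbr.size(), inr);
        long long enl = esc_get(INTEGER(nbl), nbl.size(), inl);
        std::deque<Event> evr, evl;
        for (long long e = 0; e < enr + enl; ++e) {
            if (ibt >= btype.size() || ibn >= bnt.size())
                stop("container corrupt: bifurcation stream exhausted");
            Event ev;
            ev.type = btype[ibt++];
            ev.nt = bnt[ibn++];
            ev.pos = (ev.type == EV_ERROR)
                ? int(esc_get(INTEGER(bpos), bpos.size(), ibp)) : -1;
            (e < enr ? evr : evl).push_back(ev);
        }

        std::string s(size_t(l), 'A');
        uint64_t av = d->entries[size_t(ai)];
        for (int i = k - 1; i >= 0; --i) { s[size_t(ap) + i] = rb::code_base(int(av & 3)); av >>= 2; }
        replay_right(s, int(ap), int(l), *g, evr);
        replay_left(s, int(ap), *g, evl);
        if (!evr.empty() || !evl.empty())
            stop("container corrupt: unconsumed bifurcation events");

        long long nN = esc_get(INTEGER(nn), nn.size(), inn);
        long long prev = 0;
        for (long long j = 0; j < nN; ++j) {
            prev += esc_get(INTEGER(npos), npos.size(), inp);
            if (prev < 0 || prev >= l) stop("container corrupt: N position");
            s[size_t(prev)] = 'N';
        }
        out[r] = s;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Quality smoothing
// ---------------------------------------------------------------------------

static inline int sigma_for(char q) {
    int delta = int('@') - int(q);
    return (delta <= 10) ? 2 : delta - 5;
}

static void coverage_impl(const std::string& masked, const Bloom& g,
                          std::vector<int>& cov) {
    const int k = g.k, l = int(masked.size());
    cov.assign(size_t(l), 0);
    if (l < k) return;
    // presence of each kmer window, then sliding-window sum
    std::vector<int> present(size_t(l - k + 1), 0);
    uint64_t v = rb::encode_kmer(masked.c_str(), k);
    present[0] = g.contains(v) ? 1 : 0;
    for (int j = 1; j + k <= l; ++j) {
        v = rb::next_kmer(v, rb::base_code(masked[j + k - 1]), k);
        present[size_t(j)] = g.contains(v) ? 1 : 0;
    }
    int run = 0;
    for (int i = 0; i < l; ++i) {
        if (i <= l - k) run += present[size_t(i)];
        if (i - k >= 0 && i - k <= l - k) run -= present[size_t(i - k)];
        cov[size_t(i)] = run;
    }
}

static std::string mask_n(const char* s, int l) {
    std::string m(s, size_t(l));
    for (int i = 0; i < l; ++i)
        if (rb::base_code(m[i]) < 0) m[i] = 'A';
    return m;
}

// [[Rcpp::export(name = ".rb_solid_coverage")]]
IntegerVector rb_solid_coverage(std::string read, SEXP graph) {
    XPtr<Bloom> g(graph);
    std::vector<int> cov;
    coverage_impl(mask_n(read.c_str(), int(read.size())), *g, cov);
    return wrap(cov);
}

// [[Rcpp::export(name = ".rb_smooth_block")]]
CharacterVector rb_smooth_block(CharacterVector quals, CharacterVector seqs,
                                SEXP graph) {
    XPtr<Bloom> g(graph);
    if (quals.size() != seqs.size()) stop("quality/sequence count mismatch");
    CharacterVector out(quals.size());
    std::vector<int> cov;
    for (R_xlen_t r = 0; r < quals.size(); ++r) {
        const char* q = CHAR(STRING_ELT(quals, r));
        const char* s = CHAR(STRING_ELT(seqs, r));
        int l = int(strlen(q));
        if (int(strlen(s)) != l) stop("read %lld: quality length mismatch", (long long)r + 1);
        coverage_impl(mask_n(s, l), *g, cov);
        std::string sq(q, size_t(l));
        for (int i = 0; i < l; ++i) {
            // sigma uses the original quality; step 1 caps at '@'
            char orig = sq[i];
            char capped = orig > '@' ? '@' : orig;
            sq[i] = (cov[size_t(i)] >= sigma_for(orig)) ? '@' : capped;
        }
        out[r] = sq;
    }
    return out;
}
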
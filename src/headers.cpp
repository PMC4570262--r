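#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Header delta coding.  A header is tokenized into maximal alphanumeric runs
// (fields) and single non-alphanumeric separator characters; each token is
// coded against the token at the same rank of the previous header as MATCH,
// NUM_DELTA (both numeric, |difference| < 2^15) or PREFIX (longest common
// prefix length + suffix).  The first header is coded against no tokens,
// i.e. all-PREFIX.  Numeric fields with leading zeros are treated as text so
// round trips stay byte-exact.

static const int OP_MATCH = 0, OP_DELTA = 1, OP_PREFIX = 2;

static inline bool is_alnum(unsigned char c) {
    return (c >= '0' && c <= '9') || (c >= 'A' && c <= 'Z') ||
           (c >= 'a' && c <= 'z');
}

static inline bool is_digit(unsigned char c) { return c >= '0' && c <= '9'; }

static void tokenize_impl(const char* h, int l, std::vector<std::string>& tok) {
    tok.clear();
    int i = 0;
    while (i < l) {
        if (is_alnum((unsigned char)h[i])) {
            int j = i;
            while (j < l && is_alnum((unsigned char)h[j])) ++j;
            tok.push_back(std::string(h + i, size_t(j - i)));
            i = j;
        } else {
            tok.push_back(std::string(1, h[i]));
            ++i;
        }
    }
}

// numeric = all digits, no leading zero (except "0" itself), <= 18 digits
static bool numeric_token(const std::string& t, long long& value) {
    if (t.empty() || t.size() > 18) return false;
    for (char c : t) if (!is_digit((unsigned char)c)) return false;
    if (t.size() > 1 && t[0] == '0') return false;
    value = 0;
    for (char c : t) value = value * 10 + (c - '0');
    return true;
}

static void esc_push(std::vector<int>& v, long long x) {
    if (x < 255) { v.push_back(int(x)); return; }
    v.push_back(255);
    unsigned long long u = (unsigned long long)x;
    while (u >= 128) { v.push_back(int((u & 127) | 128)); u >>= 7; }
    v.push_back(int(u));
}

static long long esc_get(const int* v, R_xlen_t n, R_xlen_t& i) {
    if (i >= n) stop("container corrupt: header stream exhausted");
    int b = v[i++];
    if (b < 255) return b;
    unsigned long long u = 0;
    int shift = 0;
    for (;;) {
        if (i >= n) stop("container corrupt: header stream exhausted");
        int c = v[i++];
        u |= (unsigned long long)(c & 127) << shift;
        if (!(c & 128)) break;
        shift += 7;
    }
    return (long long)u;
}

// [[Rcpp::export(name = ".rb_tokenize_header")]]
List rb_tokenize_header(std::string header) {
    std::vector<std::string> tok;
    tokenize_impl(header.c_str(), int(header.size()), tok);
    int n = int(tok.size());
    CharacterVector text(n);
    CharacterVector kind(n);
    for (int i = 0; i < n; ++i) {
        text[i] = tok[i];
        long long dummy;
        if (!is_alnum((unsigned char)tok[i][0])) kind[i] = "separator";
        else kind[i] = numeric_token(tok[i], dummy) ? "numeric" : "alpha";
    }
    return List::create(_["text"] = text, _["kind"] = kind);
}

// [[Rcpp::export(name = ".rb_encode_headers")]]
List rb_encode_headers(CharacterVector headers) {
    std::vector<int> ntok, op, delta, plen, slen, chars;
    std::vector<std::string> prev, cur;
    for (R_xlen_t r = 0; r < headers.size(); ++r) {
        const char* h = CHAR(STRING_ELT(headers, r));
        tokenize_impl(h, int(strlen(h)), cur);
        esc_push(ntok, (long long)cur.size());
        for (size_t t = 0; t < cur.size(); ++t) {
            const std::string& c = cur[t];
            const std::string* p = (t < prev.size()) ? &prev[t] : nullptr;
            if (p && *p == c) { op.push_back(OP_MATCH); continue; }
            long long vc, vp;
            if (p && numeric_token(c, vc) && numeric_token(*p, vp) &&
                llabs(vc - vp) < (1LL << 15)) {
                op.push_back(OP_DELTA);
                long long d = vc - vp;
                unsigned long long z = (d << 1) ^ (d >> 63); // zigzag
                while (z >= 128) { delta.push_back(int((z & 127) | 128)); z >>= 7; }
                delta.push_back(int(z));
                continue;
            }
            op.push_back(OP_PREFIX);
            size_t lcp = 0;
            if (p) {
                size_t mx = std::min(p->size(), c.size());
                while (lcp < mx && (*p)[lcp] == c[lcp]) ++lcp;
            }
            esc_push(plen, (long long)lcp);
            esc_push(slen, (long long)(c.size() - lcp));
            for (size_t i = lcp; i < c.size(); ++i)
                chars.push_back(int((unsigned char)c[i]));
        }
        prev.swap(cur);
    }
    return List::create(_["hntok"] = wrap(ntok), _["hop"] = wrap(op),
                        _["hdelta"] = wrap(delta), _["hplen"] = wrap(plen),
                        _["hslen"] = wrap(slen), _["hchar"] = wrap(chars));
}

// [[Rcpp::export(name = ".rb_decode_headers")]]
CharacterVector rb_decode_headers(List streams, double n_headers) {
    IntegerVector ntok = streams["hntok"], op = streams["hop"],
        delta = streams["hdelta"], plen = streams["hplen"],
        slen = streams["hslen"], chars = streams["hchar"];
    R_xlen_t in = 0, io = 0, id = 0, ipl = 0, isl = 0, ic = 0;
    R_xlen_t n = R_xlen_t(n_headers);
    CharacterVector out(n);
    std::vector<std::string> prev, cur;
    for (R_xlen_t r = 0; r < n; ++r) {
        long long nt = esc_get(INTEGER(ntok), ntok.size(), in);
        cur.clear();
        std::string joined;
        for (long long t = 0; t < nt; ++t) {
            if (io >= op.size()) stop("container corrupt: header op stream exhausted");
            int o = op[io++];
            const std::string* p = (size_t(t) < prev.size()) ? &prev[size_t(t)] : nullptr;
            std::string tok;
            if (o == OP_MATCH) {
                if (!p) stop("container corrupt: MATCH without previous token");
                tok = *p;
            } else if (o == OP_DELTA) {
                if (!p) stop("container corrupt: DELTA without previous token");
                long long vp;
                if (!numeric_token(*p, vp))
                    stop("container corrupt: DELTA against non-numeric token");
                unsigned long long z = 0;
                int shift = 0;
                for (;;) {
                    if (id >= delta.size()) stop("container corrupt: header delta stream");
                    int c = delta[id++];
                    z |= (unsigned long long)(c & 127) << shift;
                    if (!(c & 128)) break;
                    shift += 7;
                }
                long long d = (long long)(z >> 1) ^ -(long long)(z & 1);
                tok = std::to_string(vp + d);
            } else {
                long long lp = esc_get(INTEGER(plen), plen.size(), ipl);
                long long ls = esc_get(INTEGER(slen), slen.size(), isl);
                if (p && lp <= (long long)p->size()) tok = p->substr(0, size_t(lp));
                else if (lp > 0) stop("container corrupt: prefix length");
                for (long long i = 0; i < ls; ++i) {
                    if (ic >= chars.size()) stop("container corrupt: header char stream");
                    tok.push_back(char((unsigned char)chars[ic++]));
                }
            }
            cur.push_back(tok);
            joined += tok;
        }
        out[r] = joined;
        prev.swap(cur);
    }
    return out;
}
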
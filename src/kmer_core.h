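#ifndef READBLOOM_KMER_CORE_H
#define READBLOOM_KMER_CORE_H

#include <cstdint>
#include <string>
#include <stdexcept>

// 2-bit kmer packing: A=0, C=1, G=2, T=3, most-significant pair = leftmost
// base.  k is capped at 31 so a kmer plus its sentinel fits one uint64_t.
namespace rb {

const int KMAX = 31;

inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

inline char code_base(int b) { return "ACGT"[b & 3]; }

inline uint64_t kmer_mask(int k) {
    return (k >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
}

inline uint64_t encode_kmer(const char* s, int k) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int b = base_code(s[i]);
        if (b < 0) throw std::invalid_argument("non-ACGT base in kmer");
        v = (v << 2) | uint64_t(b);
    }
    return v;
}

inline std::string decode_kmer(uint64_t v, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = code_base(int(v & 3));
        v >>= 2;
    }
    return s;
}

// reverse pairs of bits, then complement; restricted to 2k low bits
inline uint64_t revcomp_kmer(uint64_t v, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3 - (v & 3)); // complement of least-significant base
        v >>= 2;
    }
    return r;
}

inline uint64_t canonical_kmer(uint64_t v, int k) {
    uint64_t r = revcomp_kmer(v, k);
    return r < v ? r : v;
}

// append base b on the right (successor), drop leftmost base
inline uint64_t next_kmer(uint64_t v, int b, int k) {
    return ((v << 2) | uint64_t(b)) & kmer_mask(k);
}

// prepend base b on the left (predecessor), drop rightmost base
inline uint64_t prev_kmer(uint64_t v, int b, int k) {
    return (v >> 2) | (uint64_t(b) << (2 * (k - 1)));
}

} // namespace rb

#endif
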
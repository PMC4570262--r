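#ifndef READBLOOM_BLOOM_CORE_H
#define READBLOOM_BLOOM_CORE_H

#include <cstdint>
#include <vector>
#include <cmath>
#include "kmer_core.h"

namespace rb {

// splitmix64: well-mixed 64-bit finalizer, used as the base hash
inline uint64_t mix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// Bloom filter over canonical kmers.  h probe positions come from two base
// hashes combined Kirsch-Mitzenmacher style: g_i = h1 + i*h2 (mod m).
class Bloom {
public:
    uint64_t m_bits;         // number of bit positions
    int h;                   // number of hash functions
    uint64_t seed1, seed2;
    uint64_t n_inserted;
    int k;                   // kmer length (canonicalization)
    std::vector<uint8_t> bits;

    Bloom(uint64_t m, int h_, uint64_t s1, uint64_t s2, int k_)
        : m_bits(m), h(h_), seed1(s1), seed2(s2), n_inserted(0), k(k_),
          bits((m + 7) / 8, 0) {}

    static int hashes_for_bits(double b) {
        int h = int(std::lround(b * std::log(2.0)));
        return h < 1 ? 1 : h;
    }

    void insert(uint64_t kmer) {
        uint64_t c = canonical_kmer(kmer, k);
        uint64_t h1 = mix64(c ^ seed1), h2 = mix64(c ^ seed2);
        for (int i = 0; i < h; ++i) {
            uint64_t p = (h1 + uint64_t(i) * h2) % m_bits;
            bits[p >> 3] |= uint8_t(1u << (p & 7));
        }
        ++n_inserted;
    }

    bool contains(uint64_t kmer) const {
        uint64_t c = canonical_kmer(kmer, k);
        uint64_t h1 = mix64(c ^ seed1), h2 = mix64(c ^ seed2);
        for (int i = 0; i < h; ++i) {
            uint64_t p = (h1 + uint64_t(i) * h2) % m_bits;
            if (!(bits[p >> 3] & (1u << (p & 7)))) return false;
        }
        return true;
    }

    // bitmask over {A,C,G,T} of successors of v present in the filter
    int successor_mask(uint64_t v) const {
        int m = 0;
        for (int b = 0; b < 4; ++b)
            if (contains(next_kmer(v, b, k))) m |= (1 << b);
        return m;
    }

    int predecessor_mask(uint64_t v) const {
        int m = 0;
        for (int b = 0; b < 4; ++b)
            if (contains(prev_kmer(v, b, k))) m |= (1 << b);
        return m;
    }
};

} // namespace rb

#endif
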
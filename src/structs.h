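#ifndef READBLOOM_STRUCTS_H
#define READBLOOM_STRUCTS_H

#include <cstdint>
#include <vector>
#include <unordered_map>
#include <algorithm>

namespace rb {

struct CountTable {
    int k;
    std::unordered_map<uint64_t, uint32_t> m;
};

struct SolidSet {
    int k;
    std::vector<uint64_t> v; // sorted canonical kmers
    bool contains(uint64_t canon) const {
        return std::binary_search(v.begin(), v.end(), canon);
    }
};

// Insertion-ordered set of anchor kmers, stored in the read's forward
// orientation (not canonical) so decoding needs no strand flag.
struct AnchorDict {
    int k;
    std::vector<uint64_t> entries;
    std::unordered_map<uint64_t, uint32_t> index;

    // returns index, or -1 if absent
    long long find(uint64_t v) const {
        auto it = index.find(v);
        return it == index.end() ? -1 : (long long)it->second;
    }
    uint32_t add(uint64_t v) {
        uint32_t i = uint32_t(entries.size());
        entries.push_back(v);
        index.emplace(v, i);
        return i;
    }
};

} // namespace rb

#endif
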
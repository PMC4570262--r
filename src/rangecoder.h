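#ifndef READBLOOM_RANGECODER_H
#define READBLOOM_RANGECODER_H

#include <cstdint>
#include <vector>
#include <stdexcept>

// 32-bit range coder with byte renormalization and carry handling via a
// 64-bit low register (the scheme popularized by LZMA).  Paired with an
// adaptive order-0 frequency model: per-symbol counts start at 1, grow by
// INC after each coded symbol, and are halved (floor 1) once the total
// exceeds RESCALE.  Encoder and decoder models evolve in lockstep.
namespace rb {

class RangeEncoder {
public:
    std::vector<uint8_t> out;
    RangeEncoder() : low(0), range(0xFFFFFFFFu), cache(0), cache_size(1) {}

    void encode(uint32_t cum, uint32_t freq, uint32_t tot) {
        uint32_t r = range / tot;
        low += uint64_t(r) * cum;
        range = r * freq;
        while (range < (1u << 24)) { range <<= 8; shift_low(); }
    }
    void flush() { for (int i = 0; i < 5; ++i) shift_low(); }

private:
    uint64_t low;
    uint32_t range;
    uint8_t cache;
    uint64_t cache_size;

    void shift_low() {
        if (uint32_t(low) < 0xFF000000u || (low >> 32) != 0) {
            uint8_t carry = uint8_t(low >> 32);
            do { out.push_back(uint8_t(cache + carry)); cache = 0xFF; }
            while (--cache_size);
            cache = uint8_t(low >> 24);
        }
        ++cache_size;
        low = (low & 0x00FFFFFFu) << 8;
    }
};

class RangeDecoder {
public:
    RangeDecoder(const uint8_t* data, size_t n)
        : buf(data), len(n), pos(0), code(0), range(0xFFFFFFFFu) {
        for (int i = 0; i < 5; ++i) code = (code << 8) | get_byte();
    }
    uint32_t get_freq(uint32_t tot) {
        r = range / tot;
        uint32_t f = uint32_t(code / r);
        return f >= tot ? tot - 1 : f;
    }
    void decode(uint32_t cum, uint32_t freq) {
        code -= uint64_t(cum) * r;
        range = r * freq;
        while (range < (1u << 24)) {
            code = (code << 8) | get_byte();
            range <<= 8;
        }
    }

private:
    const uint8_t* buf;
    size_t len, pos;
    uint64_t code;
    uint32_t range, r;

    uint8_t get_byte() {
        if (pos < len) return buf[pos++];
        ++pos;
        if (pos > len + 16) throw std::runtime_error("range coder: truncated input");
        return 0;
    }
};

class FreqModel {
public:
    static const uint32_t INC = 8;
    static const uint32_t RESCALE = 1u << 16;

    explicit FreqModel(int nsym) : counts(nsym, 1), total(uint32_t(nsym)) {}

    void encode_symbol(RangeEncoder& enc, int s) {
        uint32_t cum = 0;
        for (int i = 0; i < s; ++i) cum += counts[i];
        enc.encode(cum, counts[s], total);
        update(s);
    }
    int decode_symbol(RangeDecoder& dec) {
        uint32_t f = dec.get_freq(total);
        uint32_t cum = 0;
        int s = 0;
        while (cum + counts[s] <= f) cum += counts[s++];
        dec.decode(cum, counts[s]);
        update(s);
        return s;
    }

private:
    std::vector<uint32_t> counts;
    uint32_t total;

    void update(int s) {
        counts[s] += INC;
        total += INC;
        if (total > RESCALE) {
            total = 0;
            for (size_t i = 0; i < counts.size(); ++i) {
                counts[i] = (counts[i] + 1) >> 1;
                total += counts[i];
            }
        }
    }
};

} // namespace rb

#endif
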
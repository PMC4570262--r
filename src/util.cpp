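#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// CRC-32 (IEEE 802.3, reflected), table generated on first use.
static uint32_t crc_table[256];
static bool crc_ready = false;

static void crc_init() {
    for (uint32_t n = 0; n < 256; ++n) {
        uint32_t c = n;
        for (int j = 0; j < 8; ++j)
            c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
        crc_table[n] = c;
    }
    crc_ready = true;
}

// [[Rcpp::export(name = ".rb_crc32")]]
double rb_crc32(RawVector data, double init = 0) {
    if (!crc_ready) crc_init();
    uint32_t c = uint32_t(init) ^ 0xFFFFFFFFu;
    for (R_xlen_t i = 0; i < data.size(); ++i)
        c = crc_table[(c ^ data[i]) & 0xFF] ^ (c >> 8);
    return double(c ^ 0xFFFFFFFFu);
}
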
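# readbloom container format (RBF1)

All integers are little-endian. "esc-byte" streams carry values 0..254
directly; the value 255 is an escape followed by an LEB128 varint of the
true value, inside the same stream. "varint" streams are plain LEB128.
Every symbol stream is entropy-coded with an adaptive order-0 range coder
(counts start at 1, +8 per coded symbol, halved with floor 1 once the
total exceeds 2^16; 32-bit range coder with byte renormalization, 5-byte
flush). Models are re-initialized per stream and per block, so blocks are
independently decodable.

## Layout

| field | size | meaning |
|---|---|---|
| magic | 4 | `RBF1` |
| version | u8 | 1 |
| flags | u8 | bit0 FASTQ (else FASTA), bit1 lossless qualities, bit2 sequences only |
| k | u8 | kmer length (1..31) |
| T_sol | u32 | solidity threshold used (count >= T_sol is solid) |
| b | u8 | Bloom bits per solid kmer |
| n_reads | u64 | total read count |
| bloom_len | u64 | length of the serialized graph |
| bloom | bloom_len | see below |
| dict_len | u64 | length of the anchor dictionary section |
| dict | dict_len | see below |
| n_blocks | u32 | number of read blocks |
| blocks | ... | see below |
| crc32 | u32 | CRC-32 (IEEE) of every preceding byte |

## Serialized Bloom graph

`RBbf` magic (4), m bits (u64), h (u8), k (u8), hash seed1 (8 bytes),
seed2 (8 bytes), n_inserted (u64), then ceil(m/8) bytes of bit array
(bit i of the filter = byte i>>3, mask 1<<(i&7)). Probe positions are
`g_j = h1 + j*h2 mod m`, j = 0..h-1, with h1 = mix64(kmer ^ seed1),
h2 = mix64(kmer ^ seed2) and mix64 the splitmix64 finalizer. Kmers are
canonicalized (min of kmer and reverse complement under the 2-bit packed
order A=0 C=1 G=2 T=3, leftmost base most significant) before hashing.

## Anchor dictionary

n_anchors (u64), then one coded stream section (below) over alphabet 4
holding n_anchors * k base symbols, each anchor in insertion order and in
its stored (forward-read) orientation.

## Coded stream section

n_symbols (u64), n_bytes (u64), then n_bytes of range-coded data.
n_symbols = 0 means no payload bytes.

## Block

n_reads_in_block (u32), then the 12 sequence streams, in order:

| name | alphabet | per read |
|---|---|---|
| mode | 2 | 0 anchored, 1 raw |
| len | 256 | read length (esc-byte) |
| aidx | 256 | anchored: anchor dictionary index (varint) |
| apos | 256 | anchored: anchor offset (esc-byte) |
| nbr | 256 | anchored: right event count (esc-byte) |
| nbl | 256 | anchored: left event count (esc-byte) |
| btype | 2 | per event: 0 bifurcation, 1 positional |
| bnt | 4 | per event: nucleotide |
| bpos | 256 | per positional event: 0-based read offset (esc-byte) |
| nn | 256 | anchored: count of N positions (esc-byte) |
| npos | 256 | gap-coded 0-based N offsets (esc-byte) |
| raw | 5 | raw reads: bases A,C,G,T,N verbatim |

Events are emitted right walk first, then left walk, in walk order.

Unless flags bit2 (sequences only) is set, 6 header streams follow:
hntok (256, esc-byte token count), hop (3: 0 MATCH, 1 NUM_DELTA,
2 PREFIX), hdelta (256, zig-zag LEB128 numeric difference), hplen (256,
esc-byte common-prefix length), hslen (256, esc-byte suffix length),
hchar (256, suffix characters). Tokens are maximal alphanumeric runs and
single non-alphanumeric separator characters; each header is coded
against the token at the same rank of the previous header (the first
header against an empty list).

For FASTQ input (and not sequences-only), the quality section ends the
block: n_bytes (u64) + a zlib (RFC 1950) stream of the newline-terminated
concatenation of the block's quality strings (smoothed unless flags
bit1).
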
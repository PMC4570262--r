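---
title: "readbloom: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{readbloom: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readbloom)
```

## The model

`readbloom` compresses a read set against a reference it builds from the
read set itself. The reference is a de Bruijn graph over the *solid*
canonical kmers — kmers whose dataset-wide count reaches the solidity
threshold $T_{sol}$ — held in a Bloom filter. Sequencing errors generate
kmers seen once or twice; genomic kmers are seen roughly
$c\,(l-k+1)/l$ times at coverage $c$ and read length $l$. The abundance
threshold removes most error kmers, so the graph is dominated by long
simple paths and most reads can be written as: an anchor kmer
(referenced through a shared dictionary), the read length, the anchor
offset, and two short bifurcation lists.

The assumptions this rests on:

* substitution-dominated errors (Illumina-like); an insertion or
  deletion desynchronizes the kmer frame and the remainder of such a
  read degenerates into per-position difference events;
* coverage high enough for a bimodal kmer-abundance histogram; below
  roughly 10× the threshold inference falls back to a default and more
  reads go unanchored;
* reads over the A/C/G/T/N alphabet (N is masked and re-inserted by
  position; any other character is rejected).

Exactness of the graph is *not* assumed. A Bloom false positive can add
a spurious edge; the encoder then emits one more bifurcation symbol than
an exact graph would need, and the decoder — which owns the identical
filter — replays the identical walk. Losslessness of headers and
sequences is structural, not statistical.

## The walk and its state rule

Walking right from the anchor (left is the mirror image with
predecessor queries), with $S$ the graph successors of the current node
and $c$ the read's next base:

* $|S| = 1$ and $c \in S$: simple path, no symbol;
* $c \in S$, $|S| \ge 2$: true bifurcation, emit $c$;
* $c \notin S$: difference from the graph (sequencing error, rare kmer
  below threshold, or Bloom artifact), emit $(c, \text{position})$.

After the first two cases the walk continues from the read's own kmer.
After a difference event it continues from the *smallest* successor in
$S$ — i.e. it resynchronizes with the graph, so an isolated substitution
costs exactly one positional event. This was a genuinely open design
point: continuing from the read's own (non-solid) kmer is also
self-consistent, but every window overlapping the error is then absent
from the graph and one substitution cascades into up to $k-1$ positional
events; measured on the 70×/1 Mbp reference simulation it roughly
quadruples the sequence stream. The resync rule recovers the one-event
behaviour; only at a dead end ($S = \emptyset$, e.g. after an indel or
off-target read) does the walk fall back to the read's own kmer and the
cascade behaviour reappear — which is the known indel weakness of this
family of codecs. The tie-break "smallest base in $S$" occasionally
resynchronizes onto a false-positive edge; the walk then re-converges
within at most $k$ steps at the cost of a few extra events, and encoder
and decoder stay in lockstep because both apply the same rule.

Anchor selection scans kmers left to right: the first kmer already in
the dictionary wins; otherwise the leftmost *solid* kmer is appended to
the dictionary. Leftmost (rather than "any suitable") maximizes the
cheap right-extension and is deterministic. During compression the
solidity oracle is the exact solid set, not the Bloom filter: with the
filter as oracle, about one read per hundred anchors on a
false-positive *error* kmer and its walk degenerates. The dictionary
stores anchors in the read's forward orientation so no strand flag is
needed per read; the cost is that a kmer and its reverse complement can
occupy two dictionary slots.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 31 | bases | long enough that random 31-mer collisions are negligible for bacterial-to-mammalian genomes; fits one 64-bit word (2 bits/base, hard cap 31 — see below) |
| `t_sol` | `"auto"` | min. abundance | first valley of the abundance histogram, clamped to [2, 20]; the threshold is *inclusive* (count ≥ T_sol is solid) |
| `bits_per_kmer` | 12 | bits/solid kmer | ~0.3 % false-positive rate with h = round(b ln 2) = 8 hashes; the graph-size/extra-symbols trade-off flattens near 10–12 |
| `lossless_qual` | FALSE | — | lossy smoothing is the point of carrying the graph into the quality stream; lossless kept for archival use |
| `block_size` | 50000 | reads | blocks decode independently (fresh coder models per block); small enough to bound decoder memory, large enough that model adaptation amortizes |

The kmer cap at 31 (one 64-bit word) rather than 63 (two words) is a
deliberate simplification: every stated operating point uses $k = 31$,
and the single-word representation keeps hashing, counting and the walk
inner loops branch-free. Raising the cap would only change
`src/kmer_core.h`.

$T_{sol}$ inference: the histogram valley is found on the raw counts
over the *observed* abundances — the first abundance whose count drops
below its predecessor's, does not exceed its successor's, and is later
exceeded again (the genomic peak). A smoothed-histogram variant was
considered and rejected: width-3 smoothing erases the valley in exactly
the sparse, low-count histograms where the scan must still work, and
the clamp to [2, 20] already provides the robustness smoothing would
buy. Unimodal histograms (very low coverage) fall back to 3.

## Quality smoothing

With $\delta = \mathrm{code}(\texttt{'@'}) - \mathrm{code}(q)$
(character codes, equivalently Phred units; `'@'` is Phred 31):

1. qualities above `'@'` are truncated to `'@'`;
2. a position covered by at least $\sigma(q)$ solid kmers becomes `'@'`,
   where $\sigma = 2$ if $\delta \le 10$ and $\sigma = \delta - 5$
   otherwise.

$\sigma$ is computed from the *original* quality, which makes step 1 a
pure cap and the whole transform idempotent; qualities above the cap
have $\delta < 0$ and take the $\sigma = 2$ branch. Positions failing
the coverage test keep their capped value. The quality stream is then
zlib/DEFLATE-compressed (R's `memCompress`; R does not expose the
compression level, so it runs at zlib's default rather than maximum —
a marginal size effect). The transform never lowers a quality below
$\min(q, \texttt{'@'})$ and never emits a character above `'@'`;
positions with no solid support — error positions above all — keep
their evidence.

## What the simulator emulates, and what it does not

`generate_genome()` draws i.i.d. uniform A/C/G/T (an optional
`repeat_fraction` copies a leading segment over the tail to create true
graph branch points). `simulate_reads()` draws
$\lceil cG/l \rceil$ reads uniformly, half reverse-complemented,
substitutes each base with the given probability, assigns qualities from
a linear mean-Phred profile (38 falling to 32, Gaussian sd 3, clamped to
[2, 40] — an Illumina-like shape) with erroneous bases drawn from the
low tail (Phred 2–15), and returns ground truth: origin and strand in
the header (`sim.<i> <pos>/<F|R>`), planted error positions as an
attribute. Both generators use a dedicated `mt19937_64` stream, so a
(spec, seed) pair is byte-identical across sessions and platforms.

Deliberately absent: indels (the codec's known weak spot is documented,
not exercised as a guarantee), repeat structure beyond the single
tandem-copy knob, GC bias, coverage waviness, quality-correlated error
models, adapter contamination. A green test therefore establishes the
codec's contracts (losslessness, event accounting, trend directions) on
substitution-dominated uniform genomes — not performance on RNA-seq,
metagenomes or repeat-rich genomes, where the real graph has dense
branchings and more unanchored reads.

## Numerical and format choices

* **Range coder**: 32-bit, byte renormalization, carry via a 64-bit low
  register, 5-byte flush. Adaptive order-0 model per component stream
  and per block: counts start at 1, grow by 8 per symbol, halve (floor
  1) when the total passes $2^{16}$. The increment of 8 is a speed of
  adaptation choice; the coder is held to within 1 % of its own model's
  log-loss by the acceptance tests, for any increment.
* **Escape coding**: byte-alphabet streams carry 0–254 directly and
  escape larger values to an in-stream LEB128 varint, keeping the
  short-read fast path one symbol.
* **Read-order robustness is a DNA-stream property.** The
  read-order experiment measures the graph + dictionary + sequence
  streams. The simulator's headers embed the read's serial number, so
  the *header* stream's previous-header delta coding is order metadata
  by construction — shuffling inflates it for any delta coder and says
  nothing about the anchor-selection order effect the experiment is
  about.
* **Degenerate inputs**: reads shorter than $k$, all-N reads and empty
  reads are stored raw; if the whole input yields no solid kmer at the
  inferred threshold the compressor retries at $T_{sol} = 1$, and
  failing that writes an empty 1-byte filter so every read goes raw —
  the losslessness contract survives arbitrary input. `build_graph()`
  itself refuses an empty solid set, since a user calling it directly
  should lower the threshold instead.
* **Container**: little-endian, per-section byte lengths, trailing
  CRC-32 over the whole body; full byte layout in `inst/FORMAT.md`.
  FASTQ `+` separator lines are normalized to a bare `+` and FASTA is
  written one sequence per line, so "byte-identical" is guaranteed for
  files in that normal form (which the simulator and fuzzer emit).

## Limitations

* Indels and high-error chemistries: everything downstream of a frame
  shift is encoded as per-position differences.
* In-memory kmer counting (hash map): practical to ~10⁸ distinct kmers
  (a few GB); the streaming disk-based counters used by assembly
  toolkits are out of scope.
* Single-threaded; blocks are independently decodable, so
  parallelization is a structural possibility, not a feature.
* The anchor dictionary is strand-naive (forward orientation), trading
  a slightly larger dictionary for one bit per read and simpler
  decoding.
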
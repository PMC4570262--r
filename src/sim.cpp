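#include <Rcpp.h>
#include <random>
#include <cmath>
#include "kmer_core.h"
using namespace Rcpp;

// Deterministic simulator: its own mt19937_64 stream, so the same
// (spec, seed) pair is byte-identical across platforms and R sessions.

// [[Rcpp::export(name = ".rb_gen_genome")]]
std::string rb_gen_genome(double length, int seed) {
    long long n = (long long)length;
    if (n < 1) stop("genome length must be >= 1");
    std::mt19937_64 rng{uint64_t(seed)};
    std::uniform_int_distribution<int> base(0, 3);
    std::string g(size_t(n), 'A');
    for (long long i = 0; i < n; ++i) g[size_t(i)] = rb::code_base(base(rng));
    return g;
}

static char phred_char(int q) {
    if (q < 0) q = 0;
    if (q > 41) q = 41;
    return char(33 + q);
}

// [[Rcpp::export(name = ".rb_sim_reads")]]
List rb_sim_reads(std::string genome, double coverage, int read_length,
                  double substitution_rate, int seed,
                  double mean_q_start = 38.0, double mean_q_end = 32.0,
                  double sd_q = 3.0) {
    long long G = (long long)genome.size();
    if (read_length < 1 || read_length > G)
        stop("read_length must be in 1..genome length");
    if (substitution_rate < 0 || substitution_rate >= 1)
        stop("substitution_rate must be in [0, 1)");
    long long n = (long long)std::ceil(coverage * double(G) / double(read_length));
    std::mt19937_64 rng{uint64_t(seed) * 0x9E3779B97F4A7C15ULL + 1};
    std::uniform_int_distribution<long long> posd(0, G - read_length);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::uniform_int_distribution<int> shift(1, 3);
    std::uniform_int_distribution<int> lowq(2, 15);
    std::normal_distribution<double> noise(0.0, sd_q);

    CharacterVector headers(n), seqs(n), quals(n);
    List err_pos(n);
    const int L = read_length;
    std::string s(size_t(L), 'A'), q(size_t(L), '!');

    for (long long r = 0; r < n; ++r) {
        long long p = posd(rng);
        bool rev = unif(rng) < 0.5;
        if (!rev) {
            for (int i = 0; i < L; ++i) s[size_t(i)] = genome[size_t(p + i)];
        } else {
            for (int i = 0; i < L; ++i) {
                int b = rb::base_code(genome[size_t(p + L - 1 - i)]);
                s[size_t(i)] = rb::code_base(3 - b);
            }
        }
        std::vector<int> errs;
        for (int i = 0; i < L; ++i) {
            double mq = mean_q_start +
                (mean_q_end - mean_q_start) * double(i) / double(L > 1 ? L - 1 : 1);
            int qv = int(std::lround(mq + noise(rng)));
            if (unif(rng) < substitution_rate) {
                int b = rb::base_code(s[size_t(i)]);
                s[size_t(i)] = rb::code_base((b + shift(rng)) & 3);
                qv = lowq(rng);
                errs.push_back(i + 1); // 1-based
            }
            if (qv < 2) qv = 2;
            if (qv > 40) qv = 40;
            q[size_t(i)] = phred_char(qv);
        }
        headers[r] = "sim." + std::to_string(r + 1) + " " +
                     std::to_string(p + 1) + "/" + (rev ? "R" : "F");
        seqs[r] = s;
        quals[r] = q;
        err_pos[r] = wrap(errs);
    }
    return List::create(_["header"] = headers, _["sequence"] = seqs,
                        _["quality"] = quals, _["error_pos"] = err_pos,
                        _["n_reads"] = double(n));
}
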
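#ifndef CCDBG_KMER_H
#define CCDBG_KMER_H

#include <cstdint>
#include <string>
#include <stdexcept>

// 2-bit k-mer arithmetic for odd k <= 31 (A=0, C=1, G=2, T=3; the encoding is
// order-preserving per base, so integer comparison of equal-length encodings
// matches string lexicographic comparison).

namespace ccdbg {

inline int base2bits(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't': return 3;
        default: return -1;
    }
}

inline char bits2base(uint64_t b) {
    static const char tab[4] = {'A', 'C', 'G', 'T'};
    return tab[b & 3u];
}

// returns false if a non-ACGT symbol is present
inline bool encode_kmer(const char* s, int k, uint64_t& out) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) return false;
        v = (v << 2) | static_cast<uint64_t>(b);
    }
    out = v;
    return true;
}

inline uint64_t revcomp_kmer(uint64_t v, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3u - (v & 3u));
        v >>= 2;
    }
    return r;
}

inline uint64_t canonical_kmer(uint64_t v, int k, bool& forward) {
    uint64_t rc = revcomp_kmer(v, k);
    forward = v <= rc;
    return forward ? v : rc;
}

inline std::string decode_kmer(uint64_t v, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bits2base(v & 3u);
        v >>= 2;
    }
    return s;
}

// 64-bit mixing function (splitmix64 finalizer); used to order minimizers and
// to drive the fixture generators.
inline uint64_t mix64(uint64_t z) {
    z += UINT64_C(0x9E3779B97F4A7C15);
    z = (z ^ (z >> 30)) * UINT64_C(0xBF58476D1CE4E5B9);
    z = (z ^ (z >> 27)) * UINT64_C(0x94D049BB133111EB);
    return z ^ (z >> 31);
}

// Minimizer of a (canonical) k-mer: the w-mer with the smallest seeded hash,
// leftmost on ties. Returns the 2-bit encoded w-mer value.
inline uint64_t minimizer_of(uint64_t kmer, int k, int w, uint64_t seed) {
    uint64_t wmask = (w >= 32) ? ~UINT64_C(0) : ((UINT64_C(1) << (2 * w)) - 1);
    uint64_t best = 0, best_h = ~UINT64_C(0);
    int nw = k - w + 1;
    for (int i = 0; i < nw; ++i) {
        // w-mer starting at position i (0-based from the left end)
        uint64_t wm = (kmer >> (2 * (k - w - i))) & wmask;
        uint64_t h = mix64(wm ^ seed);
        if (h < best_h) { best_h = h; best = wm; }
    }
    return best;
}

// simple deterministic PRNG (splitmix64 stream)
class SplitMix64 {
public:
    explicit SplitMix64(uint64_t seed) : state_(seed) {}
    uint64_t next() {
        state_ += UINT64_C(0x9E3779B97F4A7C15);
        uint64_t z = state_;
        z = (z ^ (z >> 30)) * UINT64_C(0xBF58476D1CE4E5B9);
        z = (z ^ (z >> 27)) * UINT64_C(0x94D049BB133111EB);
        return z ^ (z >> 31);
    }
    // uniform in [0, n)
    uint64_t below(uint64_t n) { return next() % n; }
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
private:
    uint64_t state_;
};

} // namespace ccdbg

#endif
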
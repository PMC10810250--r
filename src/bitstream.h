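#ifndef CCDBG_BITSTREAM_H
#define CCDBG_BITSTREAM_H

#include <cstdint>
#include <cstring>
#include <vector>
#include <stdexcept>

// Bit order is most-significant-bit-first within bytes throughout the index
// (recorded in the serialized header), so bit streams are byte-exact across
// platforms.

namespace ccdbg {

inline int bit_length(uint64_t v) {
    // number of bits needed to write v (v >= 1): 1 + floor(log2 v)
    int b = 0;
    while (v) { ++b; v >>= 1; }
    return b;
}

class BitWriter {
public:
    std::vector<uint8_t> buf;
    uint64_t nbits = 0;

    inline void push(bool b) {
        if ((nbits & 7u) == 0) buf.push_back(0);
        if (b) buf[nbits >> 3] |= static_cast<uint8_t>(0x80u >> (nbits & 7u));
        ++nbits;
    }
    // write the low n bits of v, MSB first
    inline void write_bits(uint64_t v, int n) {
        for (int i = n - 1; i >= 0; --i) push((v >> i) & 1u);
    }
    inline void write_unary0(uint64_t z) { // z zeros then a one
        for (uint64_t i = 0; i < z; ++i) push(false);
        push(true);
    }
    // Elias gamma: (b-1) zeros, then v in b bits (leading one included)
    inline void write_gamma(uint64_t v) {
        if (v < 1) throw std::invalid_argument("gamma code requires v >= 1");
        int b = bit_length(v);
        for (int i = 0; i < b - 1; ++i) push(false);
        write_bits(v, b);
    }
    // Elias delta: gamma code of the bit length of v, then the low b-1 bits
    inline void write_delta(uint64_t v) {
        if (v < 1) throw std::invalid_argument("delta code requires v >= 1");
        int b = bit_length(v);
        write_gamma(static_cast<uint64_t>(b));
        if (b > 1) write_bits(v & ((UINT64_C(1) << (b - 1)) - 1), b - 1);
    }
};

class BitReader {
public:
    const uint8_t* buf = nullptr;
    uint64_t pos = 0;     // next bit to read
    uint64_t nbits = 0;   // total available

    BitReader() = default;
    BitReader(const uint8_t* b, uint64_t n, uint64_t start = 0)
        : buf(b), pos(start), nbits(n) {}

    inline bool read() {
        if (pos >= nbits) throw std::out_of_range("bit stream exhausted");
        bool b = (buf[pos >> 3] >> (7 - (pos & 7u))) & 1u;
        ++pos;
        return b;
    }
    inline uint64_t read_bits(int n) {
        uint64_t v = 0;
        for (int i = 0; i < n; ++i) v = (v << 1) | (read() ? 1u : 0u);
        return v;
    }
    inline uint64_t read_gamma() {
        int z = 0;
        while (!read()) ++z;
        uint64_t v = 1;
        for (int i = 0; i < z; ++i) v = (v << 1) | (read() ? 1u : 0u);
        return v;
    }
    inline uint64_t read_delta() {
        int b = static_cast<int>(read_gamma());
        uint64_t v = UINT64_C(1) << (b - 1);
        if (b > 1) v |= read_bits(b - 1);
        return v;
    }
};

// Rank-supported plain bit-vector: one absolute count per 512-bit superblock,
// per-word popcounts computed on the fly (o(m) overhead, O(1) rank).
class RankBV {
public:
    std::vector<uint64_t> words;
    uint64_t m = 0;                 // number of bits
    std::vector<uint64_t> super;    // absolute rank at each 512-bit boundary

    void assign(const std::vector<uint64_t>& w, uint64_t nbits) {
        words = w;
        m = nbits;
        build_rank();
    }
    void set_size(uint64_t nbits) {
        m = nbits;
        words.assign((nbits + 63) / 64, 0);
    }
    inline void set(uint64_t i) { words[i >> 6] |= UINT64_C(1) << (i & 63u); }
    inline bool get(uint64_t i) const {
        return (words[i >> 6] >> (i & 63u)) & 1u;
    }
    void build_rank() {
        uint64_t nsuper = words.size() / 8 + 1;
        super.assign(nsuper, 0);
        uint64_t acc = 0;
        for (size_t wi = 0; wi < words.size(); ++wi) {
            if (wi % 8 == 0) super[wi / 8] = acc;
            acc += static_cast<uint64_t>(popcount64(words[wi]));
        }
    }
    // number of ones in the 0-based half-open prefix [0, i)
    inline uint64_t rank1(uint64_t i) const {
        uint64_t wi = i >> 6;
        uint64_t r = super[wi >> 3];
        for (uint64_t j = (wi >> 3) << 3; j < wi; ++j)
            r += popcount64(words[j]);
        uint64_t rem = i & 63u;
        if (rem) r += popcount64(words[wi] & ((UINT64_C(1) << rem) - 1));
        return r;
    }
    static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
        return __builtin_popcountll(x);
#else
        int c = 0;
        while (x) { x &= x - 1; ++c; }
        return c;
#endif
    }
};

// Elias-Fano encoding of a non-decreasing sequence over universe [0, u).
// access(i) uses a select-in-word scan over the high-bits vector (no select
// directory; sequences here are short).
class EliasFano {
public:
    uint64_t n = 0, u = 0;
    int l = 0;
    std::vector<uint8_t> low;      // n * l bits, MSB-first
    std::vector<uint64_t> high;    // unary-gap coded high parts

    void build(const std::vector<uint64_t>& S, uint64_t universe) {
        n = S.size();
        u = universe < 1 ? 1 : universe;
        for (size_t i = 0; i < S.size(); ++i) {
            if (S[i] >= u) throw std::invalid_argument("Elias-Fano: value >= universe");
            if (i > 0 && S[i] < S[i - 1])
                throw std::invalid_argument("Elias-Fano: sequence not non-decreasing");
        }
        l = 0;
        if (n > 0 && u / n > 1) {
            uint64_t r = u / n;
            while ((UINT64_C(2) << l) <= r) ++l; // floor(log2(u/n))
        }
        BitWriter lw;
        uint64_t hbits = n + (n > 0 ? (S.back() >> l) : 0) + 1;
        high.assign((hbits + 63) / 64, 0);
        for (uint64_t i = 0; i < n; ++i) {
            if (l > 0) lw.write_bits(S[i] & ((UINT64_C(1) << l) - 1), l);
            uint64_t hp = (S[i] >> l) + i; // position of the i-th one
            high[hp >> 6] |= UINT64_C(1) << (hp & 63u);
        }
        low = lw.buf;
    }
    // 0-based access
    uint64_t access(uint64_t i) const {
        if (i >= n) throw std::out_of_range("Elias-Fano access out of range");
        // select the i-th one in `high` by word scan
        uint64_t seen = 0, p = 0;
        for (size_t wi = 0; wi < high.size(); ++wi) {
            int pc = RankBV::popcount64(high[wi]);
            if (seen + pc > i) {
                uint64_t w = high[wi];
                uint64_t need = i - seen;
                for (uint64_t b = 0; b < 64; ++b) {
                    if ((w >> b) & 1u) {
                        if (need == 0) { p = (static_cast<uint64_t>(wi) << 6) + b; break; }
                        --need;
                    }
                }
                break;
            }
            seen += pc;
        }
        uint64_t hi = p - i;
        uint64_t lo = 0;
        if (l > 0) {
            BitReader br(low.data(), static_cast<uint64_t>(low.size()) * 8, i * l);
            lo = br.read_bits(l);
        }
        return (hi << l) | lo;
    }
    uint64_t size_bits() const {
        return static_cast<uint64_t>(low.size()) * 8 +
               static_cast<uint64_t>(high.size()) * 64 + 128 + 8; // n,u headers + l
    }
};

} // namespace ccdbg

#endif
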
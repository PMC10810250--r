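#ifndef CCDBG_COLORSTORE_H
#define CCDBG_COLORSTORE_H

#include <cstdint>
#include <vector>
#include <algorithm>
#include <stdexcept>
#include "bitstream.h"

// The compressed inverted index over distinct colors. Each color (a strictly
// increasing list of reference ids in [1..N]) is routed by density d = |C|/N:
//   d < 1/4  -> sparse: Elias-delta of the first value, then delta-coded gaps
//   d > 3/4  -> dense:  the complement set, encoded as sparse
//   otherwise-> characteristic bit-vector of length N
// (boundary densities exactly 1/4 and 3/4 take the bit-vector route; the
// sparse/dense rules are strict inequalities). A 2-bit tag and the
// delta-coded cardinality precede each payload. Encoded colors are
// concatenated into one bit stream; an Elias-Fano directory of M+1 bit
// offsets delimits them.

namespace ccdbg {

enum ColorTag { TAG_SPARSE = 0, TAG_BITVEC = 1, TAG_DENSE = 2 };

struct ColorStore {
    uint32_t N = 0;
    uint32_t M = 0;
    std::vector<uint8_t> seq;   // concatenated encoded colors
    uint64_t total_bits = 0;
    EliasFano offsets;          // M + 1 bit positions (offsets[0] = 0)

    static int route_tag(uint64_t card, uint64_t N) {
        if (4 * card < N) return TAG_SPARSE;
        if (4 * card > 3 * N) return TAG_DENSE;
        return TAG_BITVEC;
    }

    static void encode_payload_sparse(BitWriter& bw, const std::vector<uint32_t>& C) {
        if (C.empty()) return;
        bw.write_delta(C[0]);
        for (size_t i = 1; i < C.size(); ++i)
            bw.write_delta(static_cast<uint64_t>(C[i]) - C[i - 1]);
    }

    // encodes one color (header + payload) into bw; returns the tag used
    static int encode_color(BitWriter& bw, const std::vector<uint32_t>& C, uint32_t N) {
        if (C.empty()) throw std::invalid_argument("a color is never empty");
        for (size_t i = 0; i < C.size(); ++i) {
            if (C[i] < 1 || C[i] > N) throw std::invalid_argument("color value out of [1..N]");
            if (i > 0 && C[i] <= C[i - 1])
                throw std::invalid_argument("color not strictly increasing");
        }
        int tag = route_tag(C.size(), N);
        bw.write_bits(static_cast<uint64_t>(tag), 2);
        bw.write_delta(C.size());
        if (tag == TAG_SPARSE) {
            encode_payload_sparse(bw, C);
        } else if (tag == TAG_BITVEC) {
            size_t p = 0;
            for (uint32_t j = 1; j <= N; ++j) {
                bool in = (p < C.size() && C[p] == j);
                if (in) ++p;
                bw.push(in);
            }
        } else {
            std::vector<uint32_t> comp;
            comp.reserve(N - C.size());
            size_t p = 0;
            for (uint32_t j = 1; j <= N; ++j) {
                if (p < C.size() && C[p] == j) ++p;
                else comp.push_back(j);
            }
            encode_payload_sparse(bw, comp); // empty complement -> no payload
        }
        return tag;
    }

    void build(const std::vector<std::vector<uint32_t> >& colors, uint32_t n_refs) {
        N = n_refs;
        M = static_cast<uint32_t>(colors.size());
        BitWriter bw;
        std::vector<uint64_t> offs;
        offs.reserve(M + 1);
        for (uint32_t j = 0; j < M; ++j) {
            offs.push_back(bw.nbits);
            encode_color(bw, colors[j], N);
        }
        offs.push_back(bw.nbits);
        seq = bw.buf;
        total_bits = bw.nbits;
        offsets.build(offs, total_bits + 1);
    }

    // bit extent [begin, end) of color j (1-based)
    void extent(uint32_t j, uint64_t& begin, uint64_t& end) const {
        if (j < 1 || j > M) throw std::out_of_range("invalid color id");
        begin = offsets.access(j - 1);
        end = offsets.access(j);
    }
};

// Iterator over one color with Value / Next / Next-GEQ and the N+1 sentinel.
// All three representations expose identical semantics; dense colors are
// iterated by walking the decoded complement (never materializing the color).
class ColorIter {
public:
    ColorIter() = default;

    // decode-on-demand from a store
    ColorIter(const ColorStore& cs, uint32_t color_id) {
        uint64_t begin, end;
        cs.extent(color_id, begin, end);
        BitReader br(cs.seq.data(), end, begin);
        init_from_reader(br, cs.N);
    }

    // standalone iterator over an explicit set (used for oracles/tests)
    ColorIter(const std::vector<uint32_t>& C, uint32_t N) {
        BitWriter bw;
        ColorStore::encode_color(bw, C, N);
        own_bits_ = bw.buf;
        BitReader br(own_bits_.data(), bw.nbits, 0);
        init_from_reader(br, N);
    }

    uint32_t value() const { return cur_; }
    uint32_t cardinality() const { return card_; }
    int tag() const { return tag_; }
    uint32_t sentinel() const { return N_ + 1; }

    uint32_t next() {
        if (cur_ > N_) return cur_;
        advance_past(cur_);
        return cur_;
    }

    uint32_t next_geq(uint32_t x) {
        if (cur_ >= x) return cur_;
        if (tag_ == TAG_SPARSE) {
            while (cur_ < x && cur_ <= N_) advance_past(cur_);
        } else if (tag_ == TAG_BITVEC) {
            cur_ = scan_bitvec(x);
        } else {
            seek_dense(x);
        }
        return cur_;
    }

private:
    int tag_ = TAG_SPARSE;
    uint32_t N_ = 0, card_ = 0, cur_ = 0;
    // sparse state
    BitReader br_;
    uint32_t remaining_ = 0;
    // bitvec state
    uint64_t bv_begin_ = 0;
    // dense state
    std::vector<uint32_t> comp_;
    size_t cp_ = 0;
    std::vector<uint8_t> own_bits_;

    void init_from_reader(BitReader br, uint32_t N) {
        N_ = N;
        tag_ = static_cast<int>(br.read_bits(2));
        card_ = static_cast<uint32_t>(br.read_delta());
        if (tag_ == TAG_SPARSE) {
            br_ = br;
            remaining_ = card_;
            cur_ = 0;
            advance_past(0);
        } else if (tag_ == TAG_BITVEC) {
            br_ = br;
            bv_begin_ = br.pos;
            cur_ = scan_bitvec(1);
        } else {
            uint32_t csz = N_ - card_;
            comp_.resize(csz);
            uint32_t prev = 0;
            for (uint32_t i = 0; i < csz; ++i) {
                prev += static_cast<uint32_t>(br.read_delta());
                comp_[i] = prev;
            }
            cp_ = 0;
            cur_ = 0;
            seek_dense(1);
        }
    }

    void advance_past(uint32_t v) { // sparse / generic single step
        if (tag_ == TAG_SPARSE) {
            if (remaining_ == 0) { cur_ = N_ + 1; return; }
            cur_ += static_cast<uint32_t>(br_.read_delta());
            --remaining_;
        } else if (tag_ == TAG_BITVEC) {
            cur_ = scan_bitvec(v + 1);
        } else {
            seek_dense(v + 1);
        }
    }

    uint32_t scan_bitvec(uint32_t from) { // smallest set j >= from, else N+1
        if (from < 1) from = 1;
        for (uint32_t j = from; j <= N_; ++j) {
            uint64_t p = bv_begin_ + (j - 1);
            if ((br_.buf[p >> 3] >> (7 - (p & 7u))) & 1u) return j;
        }
        return N_ + 1;
    }

    void seek_dense(uint32_t x) { // smallest member >= x, walking complement
        if (x < 1) x = 1;
        if (cur_ > 0 && cur_ >= x) return; // cursor never moves backward
        uint32_t c = x;
        while (cp_ < comp_.size() && comp_[cp_] < c) ++cp_;
        while (cp_ < comp_.size() && comp_[cp_] == c) { ++c; ++cp_; }
        cur_ = (c <= N_) ? c : N_ + 1;
    }
};

// Multi-way leapfrog intersection over p >= 1 iterators (Next-GEQ driven).
inline std::vector<uint32_t> intersect_iters(std::vector<ColorIter>& its, uint32_t N) {
    std::vector<uint32_t> out;
    if (its.empty()) throw std::invalid_argument("intersection over zero iterators");
    uint32_t candidate = its[0].value();
    while (candidate <= N) {
        bool agree = true;
        for (size_t j = 1; j < its.size(); ++j) {
            uint32_t v = its[j].next_geq(candidate);
            if (v != candidate) { candidate = v; agree = false; break; }
        }
        if (candidate > N) break;
        if (agree) {
            out.push_back(candidate);
            candidate = its[0].next();
        } else {
            candidate = its[0].next_geq(candidate);
        }
    }
    return out;
}

// Scored multi-way union: emit every reference whose summed score across the
// iterators containing it is >= t.
inline std::vector<uint32_t> union_threshold_iters(std::vector<ColorIter>& its,
                                                   const std::vector<uint64_t>& scores,
                                                   uint64_t t, uint32_t N) {
    std::vector<uint32_t> out;
    for (;;) {
        uint32_t v = N + 1;
        for (size_t j = 0; j < its.size(); ++j) v = std::min(v, its[j].value());
        if (v > N) break;
        uint64_t s = 0;
        for (size_t j = 0; j < its.size(); ++j) {
            if (its[j].value() == v) { s += scores[j]; its[j].next(); }
        }
        if (s >= t) out.push_back(v);
    }
    return out;
}

} // namespace ccdbg

#endif
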
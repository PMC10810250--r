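#include <Rcpp.h>
#include <vector>
#include "bitstream.h"
#include "colorstore.h"

using namespace Rcpp;
using ccdbg::BitWriter;
using ccdbg::BitReader;
using ccdbg::EliasFano;
using ccdbg::ColorStore;
using ccdbg::ColorIter;
using ccdbg::RankBV;

// ---- Elias delta -----------------------------------------------------

// [[Rcpp::export(name = ".delta_encode_cpp")]]
List delta_encode_cpp(NumericVector v) {
    BitWriter bw;
    for (R_xlen_t i = 0; i < v.size(); ++i) {
        double x = v[i];
        if (!(x >= 1) || x != std::floor(x))
            stop("Elias-delta is defined for positive integers only");
        bw.write_delta(static_cast<uint64_t>(x));
    }
    RawVector bits(bw.buf.size());
    std::copy(bw.buf.begin(), bw.buf.end(), bits.begin());
    return List::create(_["bits"] = bits, _["nbits"] = static_cast<double>(bw.nbits));
}

// [[Rcpp::export(name = ".delta_decode_cpp")]]
NumericVector delta_decode_cpp(RawVector bits, double nbits, double count) {
    BitReader br(RAW(bits), static_cast<uint64_t>(nbits), 0);
    R_xlen_t n = static_cast<R_xlen_t>(count);
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = static_cast<double>(br.read_delta());
    return out;
}

// ---- Elias-Fano ------------------------------------------------------

// [[Rcpp::export(name = ".ef_build_cpp")]]
SEXP ef_build_cpp(NumericVector S, double u) {
    std::vector<uint64_t> v(S.size());
    for (R_xlen_t i = 0; i < S.size(); ++i) {
        if (S[i] < 0 || S[i] != std::floor(S[i]))
            stop("Elias-Fano requires non-negative integers");
        v[i] = static_cast<uint64_t>(S[i]);
    }
    XPtr<EliasFano> xp(new EliasFano(), true);
    xp->build(v, static_cast<uint64_t>(u));
    return xp;
}

// [[Rcpp::export(name = ".ef_access_cpp")]]
NumericVector ef_access_cpp(SEXP efp, NumericVector j) {
    XPtr<EliasFano> xp(efp);
    if (!xp) stop("invalid Elias-Fano pointer");
    NumericVector out(j.size());
    for (R_xlen_t i = 0; i < j.size(); ++i) {
        double jj = j[i];
        if (jj < 1 || jj > static_cast<double>(xp->n)) stop("Elias-Fano index out of range");
        out[i] = static_cast<double>(xp->access(static_cast<uint64_t>(jj) - 1));
    }
    return out;
}

// [[Rcpp::export(name = ".ef_info_cpp")]]
List ef_info_cpp(SEXP efp) {
    XPtr<EliasFano> xp(efp);
    if (!xp) stop("invalid Elias-Fano pointer");
    return List::create(_["n"] = static_cast<double>(xp->n),
                        _["u"] = static_cast<double>(xp->u),
                        _["lowBits"] = xp->l,
                        _["sizeBits"] = static_cast<double>(xp->size_bits()));
}

// ---- single-color hybrid codec ---------------------------------------

// [[Rcpp::export(name = ".encode_color_cpp")]]
List encode_color_cpp(IntegerVector C, int N) {
    std::vector<uint32_t> v(C.begin(), C.end());
    BitWriter bw;
    int tag = ColorStore::encode_color(bw, v, static_cast<uint32_t>(N));
    RawVector bits(bw.buf.size());
    std::copy(bw.buf.begin(), bw.buf.end(), bits.begin());
    return List::create(_["tag"] = tag, _["bits"] = bits,
                        _["nbits"] = static_cast<double>(bw.nbits));
}

// [[Rcpp::export(name = ".decode_color_cpp")]]
IntegerVector decode_color_cpp(RawVector bits, double nbits, int N) {
    std::vector<uint8_t> buf(bits.begin(), bits.end());
    BitReader br(buf.data(), static_cast<uint64_t>(nbits), 0);
    int tag = static_cast<int>(br.read_bits(2));
    uint32_t card = static_cast<uint32_t>(br.read_delta());
    std::vector<uint32_t> out;
    uint32_t NN = static_cast<uint32_t>(N);
    if (tag == ccdbg::TAG_SPARSE) {
        uint32_t prev = 0;
        for (uint32_t i = 0; i < card; ++i) {
            prev += static_cast<uint32_t>(br.read_delta());
            out.push_back(prev);
        }
    } else if (tag == ccdbg::TAG_BITVEC) {
        for (uint32_t j = 1; j <= NN; ++j) if (br.read()) out.push_back(j);
    } else {
        uint32_t csz = NN - card;
        std::vector<uint32_t> comp(csz);
        uint32_t prev = 0;
        for (uint32_t i = 0; i < csz; ++i) {
            prev += static_cast<uint32_t>(br.read_delta());
            comp[i] = prev;
        }
        size_t p = 0;
        for (uint32_t j = 1; j <= NN; ++j) {
            if (p < comp.size() && comp[p] == j) ++p;
            else out.push_back(j);
        }
    }
    return IntegerVector(out.begin(), out.end());
}

// ---- standalone ColorStore -------------------------------------------

static ColorStore* get_store(SEXP xp) {
    XPtr<ColorStore> p(xp);
    if (!p) stop("invalid color store pointer");
    return p.get();
}

// [[Rcpp::export(name = ".cs_new_cpp")]]
SEXP cs_new_cpp(List colors, int N) {
    std::vector<std::vector<uint32_t> > cols(colors.size());
    for (int j = 0; j < colors.size(); ++j) {
        IntegerVector v = colors[j];
        cols[j].assign(v.begin(), v.end());
    }
    XPtr<ColorStore> xp(new ColorStore(), true);
    xp->build(cols, static_cast<uint32_t>(N));
    return xp;
}

// [[Rcpp::export(name = ".cs_info_cpp")]]
List cs_info_cpp(SEXP xp) {
    ColorStore* cs = get_store(xp);
    return List::create(_["N"] = static_cast<int>(cs->N), _["M"] = static_cast<int>(cs->M),
                        _["sequencesBits"] = static_cast<double>(cs->total_bits),
                        _["offsetsBits"] = static_cast<double>(cs->offsets.size_bits()));
}

// [[Rcpp::export(name = ".cs_decode_cpp")]]
IntegerVector cs_decode_cpp(SEXP xp, int j) {
    ColorStore* cs = get_store(xp);
    ColorIter it(*cs, static_cast<uint32_t>(j));
    std::vector<uint32_t> v;
    while (it.value() <= cs->N) { v.push_back(it.value()); it.next(); }
    return IntegerVector(v.begin(), v.end());
}

// [[Rcpp::export(name = ".cs_tag_cpp")]]
List cs_tag_cpp(SEXP xp) {
    ColorStore* cs = get_store(xp);
    IntegerVector tag(cs->M), card(cs->M);
    NumericVector bits(cs->M);
    for (uint32_t j = 1; j <= cs->M; ++j) {
        uint64_t b0, b1;
        cs->extent(j, b0, b1);
        ColorIter it(*cs, j);
        tag[j - 1] = it.tag();
        card[j - 1] = static_cast<int>(it.cardinality());
        bits[j - 1] = static_cast<double>(b1 - b0);
    }
    return List::create(_["tag"] = tag, _["cardinality"] = card, _["bits"] = bits);
}

// Next-GEQ probes, each on a fresh iterator over color j
// [[Rcpp::export(name = ".cs_next_geq_cpp")]]
IntegerVector cs_next_geq_cpp(SEXP xp, int j, IntegerVector x) {
    ColorStore* cs = get_store(xp);
    IntegerVector out(x.size());
    for (int i = 0; i < x.size(); ++i) {
        ColorIter it(*cs, static_cast<uint32_t>(j));
        out[i] = static_cast<int>(it.next_geq(static_cast<uint32_t>(std::max(0, x[i]))));
    }
    return out;
}

// Value() followed by ncalls-1 Next() calls (observes the N+1 sentinel)
// [[Rcpp::export(name = ".cs_stream_cpp")]]
IntegerVector cs_stream_cpp(SEXP xp, int j, int ncalls) {
    ColorStore* cs = get_store(xp);
    ColorIter it(*cs, static_cast<uint32_t>(j));
    IntegerVector out(ncalls);
    for (int i = 0; i < ncalls; ++i) {
        out[i] = static_cast<int>(it.value());
        it.next();
    }
    return out;
}

// [[Rcpp::export(name = ".cs_intersect_cpp")]]
IntegerVector cs_intersect_cpp(SEXP xp, IntegerVector ids) {
    ColorStore* cs = get_store(xp);
    if (ids.size() == 0) stop("intersection over zero colors");
    std::vector<ColorIter> its;
    for (int i = 0; i < ids.size(); ++i)
        its.push_back(ColorIter(*cs, static_cast<uint32_t>(ids[i])));
    std::vector<uint32_t> v = ccdbg::intersect_iters(its, cs->N);
    return IntegerVector(v.begin(), v.end());
}

// ---- ColorRank (bit-vector B + rank directory) ------------------------

// [[Rcpp::export(name = ".cr_build_cpp")]]
List cr_build_cpp(IntegerVector colorIds) {
    int m = colorIds.size();
    if (m == 0) stop("empty unitig layout");
    for (int i = 1; i < m; ++i)
        if (colorIds[i] < colorIds[i - 1])
            stop("color ids are not grouped (non-decreasing) in the unitig layout");
    RankBV bv;
    bv.set_size(static_cast<uint64_t>(m));
    int M = 1;
    for (int i = 0; i + 1 < m; ++i) {
        if (colorIds[i] != colorIds[i + 1]) { bv.set(i); ++M; }
    }
    bv.set(m - 1);
    bv.build_rank();
    RawVector words(bv.words.size() * 8);
    std::memcpy(RAW(words), bv.words.data(), bv.words.size() * 8);
    NumericVector super(bv.super.size());
    for (size_t i = 0; i < bv.super.size(); ++i) super[i] = static_cast<double>(bv.super[i]);
    return List::create(_["words"] = words, _["m"] = m, _["M"] = M, _["super"] = super);
}

static RankBV rank_from_r(RawVector words, int m) {
    RankBV bv;
    bv.m = static_cast<uint64_t>(m);
    bv.words.resize(words.size() / 8);
    std::memcpy(bv.words.data(), RAW(words), bv.words.size() * 8);
    bv.build_rank();
    return bv;
}

// number of ones in B[1, i) for each i (1-based, half-open)
// [[Rcpp::export(name = ".cr_rank1_cpp")]]
IntegerVector cr_rank1_cpp(RawVector words, int m, IntegerVector i) {
    RankBV bv = rank_from_r(words, m);
    IntegerVector out(i.size());
    for (int j = 0; j < i.size(); ++j) {
        if (i[j] < 1 || i[j] > m + 1) stop("rank position out of range [1..m+1]");
        out[j] = static_cast<int>(bv.rank1(static_cast<uint64_t>(i[j]) - 1));
    }
    return out;
}

// [[Rcpp::export(name = ".cr_bits_cpp")]]
LogicalVector cr_bits_cpp(RawVector words, int m) {
    RankBV bv = rank_from_r(words, m);
    LogicalVector out(m);
    for (int i = 0; i < m; ++i) out[i] = bv.get(static_cast<uint64_t>(i));
    return out;
}
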
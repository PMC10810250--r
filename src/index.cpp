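#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <set>
#include <vector>
#include <string>
#include <fstream>
#include <memory>
#include <cmath>
#include "kmer.h"
#include "bitstream.h"
#include "colorstore.h"

using namespace Rcpp;

// The composed ccdBG index: an order-preserving k-mer dictionary over the
// color-sorted unitigs (minimizer-bucketed, every candidate verified by
// direct sequence comparison, so lookups are exact), the 1-bit-per-unitig
// rank structure mapping unitig ids to color ids, and the hybrid compressed
// color store. Pseudoalignment algorithms and the two-pass batch mode
// operate on this structure.

namespace ccdbg {

static const uint64_t MINIMIZER_SEED = UINT64_C(0x5BD1E995C0FFEE11);
static const uint32_t INDEX_VERSION = 1;

struct Hit {
    bool found = false;
    uint32_t unitig = 0;  // 1-based
    uint32_t offset = 0;  // 0-based within unitig
    bool fwd = true;      // occurrence equals the query k-mer as given
};

struct Index {
    int k = 31, w = 15;
    uint64_t seed = MINIMIZER_SEED;
    uint32_t N = 0, m = 0, M = 0;
    uint64_t n = 0;
    std::vector<uint64_t> offsets; // m + 1 character offsets into blob
    std::string blob;              // concatenated unitig spellings
    RankBV B;
    ColorStore store;
    std::vector<std::string> ref_names;
    std::unordered_map<uint64_t, std::vector<std::pair<uint32_t, uint32_t> > > minidx;

    uint32_t unitig_len(uint32_t u) const { // u 1-based
        return static_cast<uint32_t>(offsets[u] - offsets[u - 1]);
    }
    const char* unitig_ptr(uint32_t u) const { return blob.data() + offsets[u - 1]; }

    uint32_t color_id(uint32_t u) const { // Rank1(u, B) + 1, B[1, u) half-open
        return static_cast<uint32_t>(B.rank1(u - 1)) + 1;
    }

    void build_minimizer_index() {
        minidx.clear();
        uint64_t mask = (UINT64_C(1) << (2 * k)) - 1;
        for (uint32_t u = 1; u <= m; ++u) {
            const char* s = unitig_ptr(u);
            uint32_t len = unitig_len(u);
            uint64_t e = 0;
            for (int j = 0; j < k - 1; ++j)
                e = (e << 2) | static_cast<uint64_t>(base2bits(s[j]));
            for (uint32_t p = 0; p + k <= len; ++p) {
                e = ((e << 2) | static_cast<uint64_t>(base2bits(s[p + k - 1]))) & mask;
                bool fw;
                uint64_t c = canonical_kmer(e, k, fw);
                uint64_t mm = minimizer_of(c, k, w, seed);
                minidx[mm].push_back(std::make_pair(u, p));
            }
        }
    }

    // lookup of an encoded query k-mer; bucket may be supplied by the caller
    // (streaming minimizer cache)
    Hit lookup_encoded(uint64_t e,
                       const std::vector<std::pair<uint32_t, uint32_t> >* bucket) const {
        Hit h;
        if (!bucket) return h;
        uint64_t rc = revcomp_kmer(e, k);
        for (size_t i = 0; i < bucket->size(); ++i) {
            uint32_t u = (*bucket)[i].first, p = (*bucket)[i].second;
            uint64_t s;
            encode_kmer(unitig_ptr(u) + p, k, s);
            if (s == e) { h.found = true; h.unitig = u; h.offset = p; h.fwd = true; return h; }
            if (s == rc) { h.found = true; h.unitig = u; h.offset = p; h.fwd = false; return h; }
        }
        return h;
    }

    const std::vector<std::pair<uint32_t, uint32_t> >* find_bucket(uint64_t mm) const {
        std::unordered_map<uint64_t, std::vector<std::pair<uint32_t, uint32_t> > >::const_iterator
            it = minidx.find(mm);
        return it == minidx.end() ? nullptr : &it->second;
    }

    Hit lookup_kmer(uint64_t e) const {
        bool fw;
        uint64_t c = canonical_kmer(e, k, fw);
        return lookup_encoded(e, find_bucket(minimizer_of(c, k, w, seed)));
    }
};

// ----------------------------------------------------------------------
// streaming engine
// ----------------------------------------------------------------------

struct StreamCounters {
    uint64_t cache_hits = 0;     // extension of the cached (unitig, offset)
    uint64_t bucket_reuse = 0;   // minimizer unchanged, hashing skipped
    uint64_t searches = 0;       // full minimizer searches
};

// invoke fn(position, Hit) for every k-mer window of q (invalid windows miss)
template <typename F>
void stream_sequence(const Index& idx, const std::string& q, StreamCounters& cnt, F fn) {
    int k = idx.k;
    int64_t P = static_cast<int64_t>(q.size()) - k + 1;
    if (P < 1) return;
    uint64_t mask = (UINT64_C(1) << (2 * k)) - 1;

    bool have_pos = false;
    uint32_t cu = 0, cp = 0;
    bool cfwd = true;
    bool have_mm = false;
    uint64_t last_mm = 0;
    const std::vector<std::pair<uint32_t, uint32_t> >* last_bucket = nullptr;

    uint64_t e = 0;
    int valid = 0; // number of valid trailing bases accumulated
    for (int64_t pos = 0; pos < static_cast<int64_t>(q.size()); ++pos) {
        int b = base2bits(q[pos]);
        if (b < 0) { valid = 0; e = 0; } else { e = ((e << 2) | static_cast<uint64_t>(b)) & mask; ++valid; }
        int64_t p = pos - k + 1;
        if (p < 0) continue;
        if (valid < k) {
            if (p < P) { Hit miss; fn(p, miss); have_pos = false; }
            continue;
        }
        Hit h;
        if (have_pos) {
            // try to extend the cached occurrence by one position
            if (cfwd) {
                if (cp + 1 + k <= idx.unitig_len(cu)) {
                    uint64_t s;
                    encode_kmer(idx.unitig_ptr(cu) + cp + 1, k, s);
                    if (s == e) { h.found = true; h.unitig = cu; h.offset = cp + 1; h.fwd = true; }
                }
            } else {
                if (cp >= 1) {
                    uint64_t s;
                    encode_kmer(idx.unitig_ptr(cu) + cp - 1, k, s);
                    if (s == revcomp_kmer(e, k)) { h.found = true; h.unitig = cu; h.offset = cp - 1; h.fwd = false; }
                }
            }
            if (h.found) ++cnt.cache_hits;
        }
        if (!h.found) {
            bool fw;
            uint64_t c = canonical_kmer(e, k, fw);
            uint64_t mm = minimizer_of(c, idx.k, idx.w, idx.seed);
            if (have_mm && mm == last_mm) {
                ++cnt.bucket_reuse;
            } else {
                last_bucket = idx.find_bucket(mm);
                last_mm = mm;
                have_mm = true;
                ++cnt.searches;
            }
            h = idx.lookup_encoded(e, last_bucket);
        }
        if (h.found) { have_pos = true; cu = h.unitig; cp = h.offset; cfwd = h.fwd; }
        else have_pos = false; // a miss clears only the position cache
        fn(p, h);
    }
}

// ----------------------------------------------------------------------
// serialization (little-endian, MSB-first bit streams, FNV-1a checksums)
// ----------------------------------------------------------------------

static uint64_t fnv1a(const std::vector<uint8_t>& v) {
    uint64_t h = UINT64_C(0xCBF29CE484222325);
    for (size_t i = 0; i < v.size(); ++i) {
        h ^= v[i];
        h *= UINT64_C(0x100000001B3);
    }
    return h;
}

struct Buf {
    std::vector<uint8_t> v;
    template <typename T> void put(T x) {
        const uint8_t* p = reinterpret_cast<const uint8_t*>(&x);
        v.insert(v.end(), p, p + sizeof(T));
    }
    void put_bytes(const void* p, size_t n) {
        const uint8_t* q = static_cast<const uint8_t*>(p);
        v.insert(v.end(), q, q + n);
    }
    void put_str(const std::string& s) {
        put<uint32_t>(static_cast<uint32_t>(s.size()));
        put_bytes(s.data(), s.size());
    }
};

struct Cur {
    const std::vector<uint8_t>* v;
    size_t pos = 0;
    template <typename T> T get() {
        if (pos + sizeof(T) > v->size()) stop("index file truncated");
        T x;
        std::memcpy(&x, v->data() + pos, sizeof(T));
        pos += sizeof(T);
        return x;
    }
    std::string get_str() {
        uint32_t n = get<uint32_t>();
        if (pos + n > v->size()) stop("index file truncated");
        std::string s(reinterpret_cast<const char*>(v->data() + pos), n);
        pos += n;
        return s;
    }
    void get_bytes(void* p, size_t n) {
        if (pos + n > v->size()) stop("index file truncated");
        std::memcpy(p, v->data() + pos, n);
        pos += n;
    }
};

static void write_section(std::ofstream& out, const Buf& b) {
    uint64_t len = b.v.size(), chk = fnv1a(b.v);
    out.write(reinterpret_cast<const char*>(&len), 8);
    out.write(reinterpret_cast<const char*>(b.v.data()), static_cast<std::streamsize>(len));
    out.write(reinterpret_cast<const char*>(&chk), 8);
}

static std::vector<uint8_t> read_section(std::ifstream& in) {
    uint64_t len = 0, chk = 0;
    in.read(reinterpret_cast<char*>(&len), 8);
    if (!in) stop("index file truncated");
    std::vector<uint8_t> b(len);
    in.read(reinterpret_cast<char*>(b.data()), static_cast<std::streamsize>(len));
    in.read(reinterpret_cast<char*>(&chk), 8);
    if (!in) stop("index file truncated");
    if (fnv1a(b) != chk) stop("index file checksum mismatch; refusing to load");
    return b;
}

static void ef_to_buf(Buf& b, const EliasFano& ef) {
    b.put<uint64_t>(ef.n);
    b.put<uint64_t>(ef.u);
    b.put<uint32_t>(static_cast<uint32_t>(ef.l));
    b.put<uint64_t>(ef.low.size());
    b.put_bytes(ef.low.data(), ef.low.size());
    b.put<uint64_t>(ef.high.size());
    b.put_bytes(ef.high.data(), ef.high.size() * 8);
}

static void ef_from_buf(Cur& c, EliasFano& ef) {
    ef.n = c.get<uint64_t>();
    ef.u = c.get<uint64_t>();
    ef.l = static_cast<int>(c.get<uint32_t>());
    uint64_t nl = c.get<uint64_t>();
    ef.low.resize(nl);
    c.get_bytes(ef.low.data(), nl);
    uint64_t nh = c.get<uint64_t>();
    ef.high.resize(nh);
    c.get_bytes(ef.high.data(), nh * 8);
}

void save_index(const Index& idx, const std::string& path) {
    std::ofstream out(path.c_str(), std::ios::binary);
    if (!out) stop("cannot open '%s' for writing", path.c_str());
    Buf h;
    h.put_bytes("CCXI", 4);
    h.put<uint32_t>(INDEX_VERSION);
    h.put<uint8_t>(1); // bit-order flag: MSB-first within bytes
    h.put<uint32_t>(static_cast<uint32_t>(idx.k));
    h.put<uint32_t>(static_cast<uint32_t>(idx.w));
    h.put<uint64_t>(idx.seed);
    h.put<uint32_t>(idx.N);
    h.put<uint32_t>(idx.m);
    h.put<uint32_t>(idx.M);
    h.put<uint64_t>(idx.n);
    write_section(out, h);

    Buf names;
    names.put<uint32_t>(static_cast<uint32_t>(idx.ref_names.size()));
    for (size_t i = 0; i < idx.ref_names.size(); ++i) names.put_str(idx.ref_names[i]);
    write_section(out, names);

    Buf dict;
    dict.put<uint64_t>(idx.offsets.size());
    dict.put_bytes(idx.offsets.data(), idx.offsets.size() * 8);
    dict.put<uint64_t>(idx.blob.size());
    dict.put_bytes(idx.blob.data(), idx.blob.size());
    write_section(out, dict);

    Buf bv;
    bv.put<uint64_t>(idx.B.m);
    bv.put<uint64_t>(idx.B.words.size());
    bv.put_bytes(idx.B.words.data(), idx.B.words.size() * 8);
    write_section(out, bv);

    Buf cs;
    cs.put<uint32_t>(idx.store.N);
    cs.put<uint32_t>(idx.store.M);
    cs.put<uint64_t>(idx.store.total_bits);
    cs.put<uint64_t>(idx.store.seq.size());
    cs.put_bytes(idx.store.seq.data(), idx.store.seq.size());
    ef_to_buf(cs, idx.store.offsets);
    write_section(out, cs);
    if (!out) stop("write failure on '%s'", path.c_str());
}

Index* load_index(const std::string& path) {
    std::ifstream in(path.c_str(), std::ios::binary);
    if (!in) stop("cannot open '%s'", path.c_str());
    std::vector<uint8_t> hs = read_section(in);
    Cur h{&hs};
    char magic[4];
    h.get_bytes(magic, 4);
    if (std::memcmp(magic, "CCXI", 4) != 0) stop("not a ccdbg index file");
    uint32_t version = h.get<uint32_t>();
    if (version != INDEX_VERSION) stop("unsupported index version %d", static_cast<int>(version));
    uint8_t bitorder = h.get<uint8_t>();
    if (bitorder != 1) stop("unsupported bit order flag");
    std::unique_ptr<Index> idx(new Index());
    idx->k = static_cast<int>(h.get<uint32_t>());
    idx->w = static_cast<int>(h.get<uint32_t>());
    idx->seed = h.get<uint64_t>();
    idx->N = h.get<uint32_t>();
    idx->m = h.get<uint32_t>();
    idx->M = h.get<uint32_t>();
    idx->n = h.get<uint64_t>();

    std::vector<uint8_t> ns = read_section(in);
    Cur nc{&ns};
    uint32_t nn = nc.get<uint32_t>();
    idx->ref_names.resize(nn);
    for (uint32_t i = 0; i < nn; ++i) idx->ref_names[i] = nc.get_str();

    std::vector<uint8_t> ds = read_section(in);
    Cur dc{&ds};
    uint64_t no = dc.get<uint64_t>();
    idx->offsets.resize(no);
    dc.get_bytes(idx->offsets.data(), no * 8);
    uint64_t nb = dc.get<uint64_t>();
    idx->blob.resize(nb);
    dc.get_bytes(&idx->blob[0], nb);

    std::vector<uint8_t> bs = read_section(in);
    Cur bc{&bs};
    uint64_t bm = bc.get<uint64_t>();
    uint64_t nw = bc.get<uint64_t>();
    std::vector<uint64_t> words(nw);
    bc.get_bytes(words.data(), nw * 8);
    idx->B.assign(words, bm);

    std::vector<uint8_t> css = read_section(in);
    Cur cc{&css};
    idx->store.N = cc.get<uint32_t>();
    idx->store.M = cc.get<uint32_t>();
    idx->store.total_bits = cc.get<uint64_t>();
    uint64_t sl = cc.get<uint64_t>();
    idx->store.seq.resize(sl);
    cc.get_bytes(idx->store.seq.data(), sl);
    ef_from_buf(cc, idx->store.offsets);

    idx->build_minimizer_index();
    return idx.release();
}

} // namespace ccdbg

using ccdbg::Index;
using ccdbg::Hit;
using ccdbg::ColorIter;
using ccdbg::StreamCounters;

static Index* get_index(SEXP xp) {
    Rcpp::XPtr<Index> p(xp);
    if (!p) stop("invalid (nil) index pointer; rebuild or reload the index");
    return p.get();
}

// [[Rcpp::export(name = ".idx_build_cpp")]]
SEXP idx_build_cpp(CharacterVector unitigs, IntegerVector colorIds, List colors,
                   int N, int k, int w, CharacterVector refNames) {
    if (w >= k) stop("minimizer length w must be smaller than k");
    if (w < 1) stop("minimizer length w must be positive");
    Rcpp::XPtr<Index> xp(new Index(), true);
    Index& idx = *xp;
    idx.k = k;
    idx.w = w;
    idx.N = static_cast<uint32_t>(N);
    idx.m = static_cast<uint32_t>(unitigs.size());
    idx.M = static_cast<uint32_t>(colors.size());

    // dictionary blob in the color-sorted order given (order-preserving)
    idx.offsets.assign(1, 0);
    uint64_t n = 0;
    int last_color = 0;
    for (uint32_t u = 0; u < idx.m; ++u) {
        std::string s = as<std::string>(unitigs[u]);
        if (static_cast<int>(s.size()) < k) stop("unitig shorter than k");
        idx.blob += s;
        idx.offsets.push_back(idx.blob.size());
        n += s.size() - k + 1;
        int c = colorIds[u];
        if (c < last_color) stop("unitigs are not grouped by color id");
        last_color = c;
    }
    idx.n = n;

    // bit-vector B: set at the last unitig of every color group and at m
    idx.B.set_size(idx.m);
    for (uint32_t u = 0; u + 1 < idx.m; ++u)
        if (colorIds[u] != colorIds[u + 1]) idx.B.set(u);
    if (idx.m > 0) idx.B.set(idx.m - 1);
    idx.B.build_rank();

    std::vector<std::vector<uint32_t> > cols(colors.size());
    for (int j = 0; j < colors.size(); ++j) {
        IntegerVector v = colors[j];
        cols[j].assign(v.begin(), v.end());
    }
    idx.store.build(cols, idx.N);

    idx.ref_names.resize(refNames.size());
    for (int i = 0; i < refNames.size(); ++i) idx.ref_names[i] = as<std::string>(refNames[i]);

    idx.build_minimizer_index();
    return xp;
}

// [[Rcpp::export(name = ".idx_info_cpp")]]
List idx_info_cpp(SEXP xp) {
    Index* idx = get_index(xp);
    return List::create(_["k"] = idx->k, _["w"] = idx->w,
                        _["N"] = static_cast<int>(idx->N),
                        _["m"] = static_cast<int>(idx->m),
                        _["M"] = static_cast<int>(idx->M),
                        _["n"] = static_cast<double>(idx->n),
                        _["refNames"] = wrap(idx->ref_names));
}

// [[Rcpp::export(name = ".idx_save_cpp")]]
void idx_save_cpp(SEXP xp, std::string path) { ccdbg::save_index(*get_index(xp), path); }

// [[Rcpp::export(name = ".idx_load_cpp")]]
SEXP idx_load_cpp(std::string path) {
    Rcpp::XPtr<Index> p(ccdbg::load_index(path), true);
    return p;
}

// [[Rcpp::export(name = ".idx_unitigs_cpp")]]
CharacterVector idx_unitigs_cpp(SEXP xp) {
    Index* idx = get_index(xp);
    CharacterVector out(idx->m);
    for (uint32_t u = 1; u <= idx->m; ++u)
        out[u - 1] = std::string(idx->unitig_ptr(u), idx->unitig_len(u));
    return out;
}

// [[Rcpp::export(name = ".idx_bits_cpp")]]
LogicalVector idx_bits_cpp(SEXP xp) {
    Index* idx = get_index(xp);
    LogicalVector out(idx->m);
    for (uint32_t i = 0; i < idx->m; ++i) out[i] = idx->B.get(i);
    return out;
}

// [[Rcpp::export(name = ".idx_color_id_cpp")]]
IntegerVector idx_color_id_cpp(SEXP xp, IntegerVector i) {
    Index* idx = get_index(xp);
    IntegerVector out(i.size());
    for (int j = 0; j < i.size(); ++j) {
        if (i[j] < 1 || static_cast<uint32_t>(i[j]) > idx->m)
            stop("unitig id out of range [1..m]");
        out[j] = static_cast<int>(idx->color_id(static_cast<uint32_t>(i[j])));
    }
    return out;
}

// [[Rcpp::export(name = ".idx_color_set_cpp")]]
IntegerVector idx_color_set_cpp(SEXP xp, int j) {
    Index* idx = get_index(xp);
    ColorIter it(idx->store, static_cast<uint32_t>(j));
    std::vector<uint32_t> v;
    while (it.value() <= idx->N) { v.push_back(it.value()); it.next(); }
    return IntegerVector(v.begin(), v.end());
}

// per-color accounting for the density-decile statistics report
// [[Rcpp::export(name = ".idx_color_stats_cpp")]]
List idx_color_stats_cpp(SEXP xp) {
    Index* idx = get_index(xp);
    int M = static_cast<int>(idx->M);
    IntegerVector tag(M), card(M);
    NumericVector bits(M);
    for (int j = 1; j <= M; ++j) {
        uint64_t b0, b1;
        idx->store.extent(static_cast<uint32_t>(j), b0, b1);
        ColorIter it(idx->store, static_cast<uint32_t>(j));
        tag[j - 1] = it.tag();
        card[j - 1] = static_cast<int>(it.cardinality());
        bits[j - 1] = static_cast<double>(b1 - b0);
    }
    return List::create(_["tag"] = tag, _["cardinality"] = card, _["bits"] = bits,
                        _["offsetsBits"] = static_cast<double>(idx->store.offsets.size_bits()),
                        _["sequencesBits"] = static_cast<double>(idx->store.total_bits));
}

// [[Rcpp::export(name = ".idx_lookup_cpp")]]
List idx_lookup_cpp(SEXP xp, CharacterVector kmers) {
    Index* idx = get_index(xp);
    int n = kmers.size();
    IntegerVector unitig(n, NA_INTEGER), offset(n, NA_INTEGER);
    LogicalVector fwd(n, NA_LOGICAL);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        if (static_cast<int>(s.size()) != idx->k)
            stop("k-mer length %d does not match index k = %d",
                 static_cast<int>(s.size()), idx->k);
        uint64_t e;
        if (!ccdbg::encode_kmer(s.c_str(), idx->k, e)) continue; // non-ACGT: absent
        Hit h = idx->lookup_kmer(e);
        if (h.found) {
            unitig[i] = static_cast<int>(h.unitig);
            offset[i] = static_cast<int>(h.offset);
            fwd[i] = h.fwd;
        }
    }
    return List::create(_["unitig"] = unitig, _["offset"] = offset, _["forward"] = fwd);
}

// [[Rcpp::export(name = ".idx_streaming_lookup_cpp")]]
List idx_streaming_lookup_cpp(SEXP xp, std::string q) {
    Index* idx = get_index(xp);
    int64_t P = static_cast<int64_t>(q.size()) - idx->k + 1;
    if (P < 1)
        return List::create(_["unitig"] = IntegerVector(0), _["offset"] = IntegerVector(0),
                            _["forward"] = LogicalVector(0), _["cacheHits"] = 0.0,
                            _["bucketReuse"] = 0.0, _["searches"] = 0.0,
                            _["tooShort"] = true);
    IntegerVector unitig(P, NA_INTEGER), offset(P, NA_INTEGER);
    LogicalVector fwd(P, NA_LOGICAL);
    StreamCounters cnt;
    ccdbg::stream_sequence(*idx, q, cnt, [&](int64_t p, const Hit& h) {
        if (h.found) {
            unitig[p] = static_cast<int>(h.unitig);
            offset[p] = static_cast<int>(h.offset);
            fwd[p] = h.fwd;
        }
    });
    return List::create(_["unitig"] = unitig, _["offset"] = offset, _["forward"] = fwd,
                        _["cacheHits"] = static_cast<double>(cnt.cache_hits),
                        _["bucketReuse"] = static_cast<double>(cnt.bucket_reuse),
                        _["searches"] = static_cast<double>(cnt.searches),
                        _["tooShort"] = false);
}

// ----------------------------------------------------------------------
// pseudoalignment
// ----------------------------------------------------------------------

namespace {

// distinct unitigs / distinct sorted color ids touched by the positive
// k-mers of one read, plus per-unitig positive-k-mer scores
struct ReadScan {
    int64_t n_kmers = 0;
    int64_t positives = 0;
    std::map<uint32_t, uint64_t> unitig_score; // unitig id -> positive k-mers
    std::vector<uint32_t> color_ids;           // sorted distinct
    std::map<uint32_t, uint64_t> color_score;  // color id -> summed score
};

ReadScan scan_read(const Index& idx, const std::string& q) {
    ReadScan rs;
    int64_t P = static_cast<int64_t>(q.size()) - idx.k + 1;
    if (P < 1) return rs;
    rs.n_kmers = P;
    StreamCounters cnt;
    ccdbg::stream_sequence(idx, q, cnt, [&](int64_t, const Hit& h) {
        if (h.found) {
            ++rs.positives;
            ++rs.unitig_score[h.unitig];
        }
    });
    for (std::map<uint32_t, uint64_t>::const_iterator it = rs.unitig_score.begin();
         it != rs.unitig_score.end(); ++it) {
        uint32_t c = idx.color_id(it->first);
        rs.color_score[c] += it->second;
    }
    for (std::map<uint32_t, uint64_t>::const_iterator it = rs.color_score.begin();
         it != rs.color_score.end(); ++it)
        rs.color_ids.push_back(it->first);
    return rs;
}

std::vector<uint32_t> intersect_color_ids(const Index& idx,
                                          const std::vector<uint32_t>& cids) {
    std::vector<ColorIter> its;
    its.reserve(cids.size());
    for (size_t j = 0; j < cids.size(); ++j) its.push_back(ColorIter(idx.store, cids[j]));
    return ccdbg::intersect_iters(its, idx.N);
}

} // namespace

// [[Rcpp::export(name = ".query_full_cpp")]]
List query_full_cpp(SEXP xp, CharacterVector reads) {
    Index* idx = get_index(xp);
    int R = reads.size();
    List refs(R);
    NumericVector nk(R), pos(R), ncol(R);
    for (int r = 0; r < R; ++r) {
        ReadScan rs = scan_read(*idx, as<std::string>(reads[r]));
        std::vector<uint32_t> res;
        if (!rs.color_ids.empty()) res = intersect_color_ids(*idx, rs.color_ids);
        refs[r] = IntegerVector(res.begin(), res.end());
        nk[r] = static_cast<double>(rs.n_kmers);
        pos[r] = static_cast<double>(rs.positives);
        ncol[r] = static_cast<double>(rs.color_ids.size());
    }
    return List::create(_["refs"] = refs, _["nKmers"] = nk, _["positives"] = pos,
                        _["nColors"] = ncol);
}

// [[Rcpp::export(name = ".query_threshold_cpp")]]
List query_threshold_cpp(SEXP xp, CharacterVector reads, double tau, bool s_positive) {
    Index* idx = get_index(xp);
    if (!(tau > 0.0 && tau <= 1.0)) stop("threshold tau must be in (0, 1]");
    // exact integer threshold: tau scaled to parts-per-million, then
    // t = ceil(s * tau) without floating-point comparisons
    uint64_t tau_ppm = static_cast<uint64_t>(std::llround(tau * 1e6));
    int R = reads.size();
    List refs(R);
    NumericVector nk(R), pos(R), ncol(R);
    for (int r = 0; r < R; ++r) {
        ReadScan rs = scan_read(*idx, as<std::string>(reads[r]));
        std::vector<uint32_t> res;
        if (rs.positives > 0) {
            uint64_t s = s_positive ? static_cast<uint64_t>(rs.positives)
                                    : static_cast<uint64_t>(rs.n_kmers);
            uint64_t t = (s * tau_ppm + 999999) / 1000000;
            if (t < 1) t = 1;
            std::vector<ColorIter> its;
            std::vector<uint64_t> scores;
            for (std::map<uint32_t, uint64_t>::const_iterator it = rs.color_score.begin();
                 it != rs.color_score.end(); ++it) {
                its.push_back(ColorIter(idx->store, it->first));
                scores.push_back(it->second);
            }
            res = ccdbg::union_threshold_iters(its, scores, t, idx->N);
        }
        refs[r] = IntegerVector(res.begin(), res.end());
        nk[r] = static_cast<double>(rs.n_kmers);
        pos[r] = static_cast<double>(rs.positives);
        ncol[r] = static_cast<double>(rs.color_ids.size());
    }
    return List::create(_["refs"] = refs, _["nKmers"] = nk, _["positives"] = pos,
                        _["nColors"] = ncol);
}

// [[Rcpp::export(name = ".query_skip_cpp")]]
List query_skip_cpp(SEXP xp, CharacterVector reads, int on_miss, int on_unexpected,
                    int back_off_limit) {
    // on_miss: 0 = query-next, 1 = back-off
    // on_unexpected: 0 = query-next, 1 = back-off, 2 = aggressive-jump
    Index* idx = get_index(xp);
    int k = idx->k;
    int R = reads.size();
    List refs(R), confirmed(R);
    NumericVector queries(R), nk(R);
    for (int r = 0; r < R; ++r) {
        std::string q = as<std::string>(reads[r]);
        int64_t P = static_cast<int64_t>(q.size()) - k + 1;
        std::vector<uint32_t> res;
        std::vector<int> conf_pos;
        uint64_t nq = 0;
        if (P >= 1) {
            std::vector<char> state(P, 0);
            std::vector<Hit> memo(P);
            uint64_t mask = (UINT64_C(1) << (2 * k)) - 1;
            auto q_at = [&](int64_t p) -> const Hit& {
                if (!state[p]) {
                    state[p] = 1;
                    ++nq;
                    uint64_t e;
                    if (ccdbg::encode_kmer(q.data() + p, k, e)) memo[p] = idx->lookup_kmer(e);
                }
                return memo[p];
            };
            (void)mask;
            std::set<uint32_t> units;
            auto confirm = [&](int64_t p, const Hit& h) {
                conf_pos.push_back(static_cast<int>(p));
                units.insert(h.unitig);
            };
            int64_t cur = 0;
            while (cur < P) {
                const Hit h0 = q_at(cur);
                if (!h0.found) { ++cur; continue; }
                confirm(cur, h0);
                int64_t anchor_pos = cur;
                Hit anchor = h0;
                bool rejump = true;
                while (rejump) {
                    rejump = false;
                    int64_t rem = anchor.fwd
                        ? static_cast<int64_t>(idx->unitig_len(anchor.unitig)) - k - anchor.offset
                        : static_cast<int64_t>(anchor.offset);
                    int64_t jump = std::min(rem, P - 1 - anchor_pos);
                    if (jump <= 0) { cur = anchor_pos + 1; break; }
                    int64_t d = jump;
                    int attempts = 0;
                    for (;;) {
                        int64_t target = anchor_pos + d;
                        const Hit h2 = q_at(target);
                        if (h2.found) {
                            confirm(target, h2);
                            if (h2.unitig == anchor.unitig) { cur = target + 1; break; }
                            if (on_unexpected == 2) { // aggressive-jump
                                anchor_pos = target;
                                anchor = h2;
                                rejump = true;
                                break;
                            }
                            if (on_unexpected == 1 && attempts < back_off_limit && d > 1) {
                                ++attempts;
                                d = std::max<int64_t>(1, d / 2);
                                continue;
                            }
                            cur = target + 1;
                            break;
                        } else {
                            if (on_miss == 1 && attempts < back_off_limit && d > 1) {
                                ++attempts;
                                d = std::max<int64_t>(1, d / 2);
                                continue;
                            }
                            cur = target + 1;
                            break;
                        }
                    }
                }
            }
            if (!units.empty()) {
                std::set<uint32_t> cids;
                for (std::set<uint32_t>::const_iterator it = units.begin(); it != units.end(); ++it)
                    cids.insert(idx->color_id(*it));
                std::vector<uint32_t> cv(cids.begin(), cids.end());
                res = intersect_color_ids(*idx, cv);
            }
        }
        refs[r] = IntegerVector(res.begin(), res.end());
        std::sort(conf_pos.begin(), conf_pos.end());
        confirmed[r] = IntegerVector(conf_pos.begin(), conf_pos.end());
        queries[r] = static_cast<double>(nq);
        nk[r] = static_cast<double>(P < 1 ? 0 : P);
    }
    return List::create(_["refs"] = refs, _["confirmed"] = confirmed,
                        _["queries"] = queries, _["nKmers"] = nk);
}

// [[Rcpp::export(name = ".query_two_pass_cpp")]]
List query_two_pass_cpp(SEXP xp, CharacterVector reads) {
    Index* idx = get_index(xp);
    int R = reads.size();
    // pass 1: color-id lists (no color decoding), collated by identical list
    std::map<std::vector<uint32_t>, std::vector<int> > groups; // lexicographic sort
    NumericVector nk(R), pos(R), ncol(R);
    std::vector<std::vector<uint32_t> > lists(R);
    for (int r = 0; r < R; ++r) {
        ReadScan rs = scan_read(*idx, as<std::string>(reads[r]));
        nk[r] = static_cast<double>(rs.n_kmers);
        pos[r] = static_cast<double>(rs.positives);
        ncol[r] = static_cast<double>(rs.color_ids.size());
        lists[r] = rs.color_ids;
        if (!rs.color_ids.empty()) groups[rs.color_ids].push_back(r);
    }
    // pass 2: intersect each distinct non-empty list exactly once
    List refs(R);
    IntegerVector empty(0);
    for (int r = 0; r < R; ++r) refs[r] = empty;
    double n_intersections = 0;
    for (std::map<std::vector<uint32_t>, std::vector<int> >::const_iterator it = groups.begin();
         it != groups.end(); ++it) {
        std::vector<uint32_t> res = intersect_color_ids(*idx, it->first);
        ++n_intersections;
        IntegerVector rv(res.begin(), res.end());
        for (size_t j = 0; j < it->second.size(); ++j) refs[it->second[j]] = rv;
    }
    return List::create(_["refs"] = refs, _["nKmers"] = nk, _["positives"] = pos,
                        _["nColors"] = ncol, _["intersections"] = n_intersections);
}

// colors of every positive k-mer of a read, decoded one by one (the naive
// composition Color(x); used by high-level helpers, not by the query modes)
// [[Rcpp::export(name = ".idx_kmer_color_cpp")]]
List idx_kmer_color_cpp(SEXP xp, CharacterVector kmers) {
    Index* idx = get_index(xp);
    int n = kmers.size();
    List out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        if (static_cast<int>(s.size()) != idx->k)
            stop("k-mer length does not match index k");
        uint64_t e;
        IntegerVector v(0);
        if (ccdbg::encode_kmer(s.c_str(), idx->k, e)) {
            Hit h = idx->lookup_kmer(e);
            if (h.found) v = idx_color_set_cpp(xp, static_cast<int>(idx->color_id(h.unitig)));
        }
        out[i] = v;
    }
    return out;
}
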
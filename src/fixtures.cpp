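#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <cmath>
#include "kmer.h"

using namespace Rcpp;
using ccdbg::SplitMix64;

// Synthetic bacterial pangenome: N haplotypes derived from one seeded base
// genome through a pool of point and indel variants, each with a population
// frequency drawn uniformly on (0,1). A reference carries a variant with
// probability equal to that frequency, so color densities span the whole
// (0,1] spectrum -- from singleton colors (private variants) through
// mid-density colors (common variants) up to >90%-dense colors (conserved
// backbone), the regime the complemented encoding targets.

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

struct Variant {
    uint64_t pos;        // 0-based position in the base genome
    int type;            // 0 = SNP, 1 = insertion, 2 = deletion
    char alt;            // SNP alternate base
    std::string ins;     // inserted sequence
    uint64_t del_len;
    double freq;
};

bool carries(uint64_t seed, size_t variant_idx, int ref_idx, double freq) {
    uint64_t h = ccdbg::mix64(seed ^ (static_cast<uint64_t>(variant_idx) * UINT64_C(1000003) +
                                      static_cast<uint64_t>(ref_idx) * UINT64_C(0x9E3779B9)));
    return (h >> 11) * (1.0 / 9007199254740992.0) < freq;
}

} // namespace

// [[Rcpp::export(name = ".gen_pangenome_cpp")]]
List gen_pangenome_cpp(int N, double L, double mu, double indel_rate,
                       double indel_mean, double seed_in) {
    if (N < 1) stop("need at least one reference");
    if (L < 1) stop("base genome length must be positive");
    if (mu < 0 || mu >= 1 || indel_rate < 0 || indel_rate >= 1 || mu + indel_rate >= 1)
        stop("degenerate variant rates");
    if (indel_mean < 1) stop("mean indel length must be >= 1");
    uint64_t seed = static_cast<uint64_t>(seed_in);
    uint64_t Lu = static_cast<uint64_t>(L);

    SplitMix64 rng(ccdbg::mix64(seed ^ UINT64_C(0xBA5E6E0)));
    std::string base(Lu, 'A');
    for (uint64_t p = 0; p < Lu; ++p) base[p] = BASES[rng.below(4)];

    // variant pool over the base genome
    std::vector<Variant> pool;
    SplitMix64 vr(ccdbg::mix64(seed ^ UINT64_C(0x5A17)));
    for (uint64_t p = 0; p < Lu; ++p) {
        double u = vr.unif();
        if (u < mu) {
            Variant v;
            v.pos = p;
            v.type = 0;
            int cur = ccdbg::base2bits(base[p]);
            v.alt = BASES[(cur + 1 + static_cast<int>(vr.below(3))) % 4];
            v.del_len = 0;
            v.freq = vr.unif();
            pool.push_back(v);
        } else if (u < mu + indel_rate) {
            Variant v;
            v.pos = p;
            v.type = (vr.below(2) == 0) ? 1 : 2;
            uint64_t len = 1;
            double cont = 1.0 - 1.0 / indel_mean;
            while (vr.unif() < cont && len < 10 * static_cast<uint64_t>(indel_mean) + 10) ++len;
            if (v.type == 1) {
                v.ins.resize(len);
                for (uint64_t j = 0; j < len; ++j) v.ins[j] = BASES[vr.below(4)];
                v.del_len = 0;
            } else {
                v.del_len = len;
            }
            v.freq = vr.unif();
            pool.push_back(v);
        }
    }

    CharacterVector seqs(N);
    for (int i = 0; i < N; ++i) {
        std::string s;
        s.reserve(Lu + Lu / 10);
        size_t vi = 0;
        uint64_t p = 0;
        while (p < Lu) {
            while (vi < pool.size() && pool[vi].pos < p) ++vi;
            if (vi < pool.size() && pool[vi].pos == p) {
                const Variant& v = pool[vi];
                ++vi;
                if (carries(seed, vi - 1, i, v.freq)) {
                    if (v.type == 0) {
                        s.push_back(v.alt);
                        ++p;
                    } else if (v.type == 1) {
                        s += v.ins;
                        s.push_back(base[p]);
                        ++p;
                    } else {
                        p += v.del_len; // deletion: skip bases
                    }
                } else {
                    s.push_back(base[p]);
                    ++p;
                }
            } else {
                s.push_back(base[p]);
                ++p;
            }
        }
        seqs[i] = s;
    }

    int nv = static_cast<int>(pool.size());
    NumericVector vpos(nv), vfreq(nv), vlen(nv);
    CharacterVector vtype(nv);
    for (int j = 0; j < nv; ++j) {
        vpos[j] = static_cast<double>(pool[j].pos + 1);
        vfreq[j] = pool[j].freq;
        vtype[j] = pool[j].type == 0 ? "snp" : (pool[j].type == 1 ? "ins" : "del");
        vlen[j] = pool[j].type == 0 ? 1.0
                 : (pool[j].type == 1 ? static_cast<double>(pool[j].ins.size())
                                      : static_cast<double>(pool[j].del_len));
    }
    return List::create(_["sequences"] = seqs,
                        _["variants"] = List::create(_["pos"] = vpos, _["type"] = vtype,
                                                     _["length"] = vlen, _["freq"] = vfreq));
}

// [[Rcpp::export(name = ".sim_reads_cpp")]]
List sim_reads_cpp(CharacterVector refs, int k, int read_len, int n_reads,
                   double positive_fraction, double error_rate, double seed_in) {
    if (read_len < k) stop("read length must be >= k");
    if (n_reads < 0) stop("negative read count");
    if (positive_fraction < 0 || positive_fraction > 1) stop("positive fraction must be in [0,1]");
    if (error_rate < 0 || error_rate >= 1) stop("error rate must be in [0,1)");
    uint64_t seed = static_cast<uint64_t>(seed_in);
    uint64_t mask = (UINT64_C(1) << (2 * k)) - 1;

    // canonical k-mer content of the reference collection
    std::unordered_set<uint64_t> kset;
    std::vector<std::string> R(refs.size());
    std::vector<int> eligible;
    for (int i = 0; i < refs.size(); ++i) {
        R[i] = as<std::string>(refs[i]);
        if (static_cast<int>(R[i].size()) >= read_len) eligible.push_back(i);
        const std::string& s = R[i];
        uint64_t e = 0;
        int valid = 0;
        for (size_t p = 0; p < s.size(); ++p) {
            int b = ccdbg::base2bits(s[p]);
            if (b < 0) { valid = 0; e = 0; continue; }
            e = ((e << 2) | static_cast<uint64_t>(b)) & mask;
            if (++valid >= k) {
                bool fw;
                kset.insert(ccdbg::canonical_kmer(e, k, fw));
            }
        }
    }

    int n_pos = static_cast<int>(std::lround(n_reads * positive_fraction));
    if (n_pos > 0 && eligible.empty())
        stop("no reference is long enough to draw positive reads from");

    SplitMix64 rng(ccdbg::mix64(seed ^ UINT64_C(0x4EAD5)));
    CharacterVector seqs(n_reads), names(n_reads);
    IntegerVector origin(n_reads), start(n_reads);
    LogicalVector revstrand(n_reads);
    for (int r = 0; r < n_reads; ++r) {
        names[r] = "read_" + std::to_string(r + 1);
        if (r < n_pos) {
            int ri = eligible[rng.below(eligible.size())];
            const std::string& src = R[ri];
            uint64_t p0 = rng.below(src.size() - read_len + 1);
            std::string rd = src.substr(p0, read_len);
            bool rev = rng.below(2) == 1;
            if (rev) {
                std::string rc(rd.rbegin(), rd.rend());
                for (size_t j = 0; j < rc.size(); ++j) {
                    int b = ccdbg::base2bits(rc[j]);
                    rc[j] = b < 0 ? 'N' : "TGCA"[b];
                }
                rd = rc;
            }
            if (error_rate > 0) {
                for (int j = 0; j < read_len; ++j) {
                    if (rng.unif() < error_rate) {
                        int cur = ccdbg::base2bits(rd[j]);
                        if (cur >= 0) rd[j] = BASES[(cur + 1 + static_cast<int>(rng.below(3))) % 4];
                    }
                }
            }
            seqs[r] = rd;
            origin[r] = ri + 1;
            start[r] = static_cast<int>(p0);
            revstrand[r] = rev;
        } else {
            // negative read: rejection-sample until k-mer-disjoint from the index
            bool ok = false;
            std::string rd(read_len, 'A');
            for (int attempt = 0; attempt < 10000 && !ok; ++attempt) {
                for (int j = 0; j < read_len; ++j) rd[j] = BASES[rng.below(4)];
                ok = true;
                uint64_t e = 0;
                for (int j = 0; j < read_len; ++j) {
                    e = ((e << 2) | static_cast<uint64_t>(ccdbg::base2bits(rd[j]))) & mask;
                    if (j >= k - 1) {
                        bool fw;
                        if (kset.count(ccdbg::canonical_kmer(e, k, fw))) { ok = false; break; }
                    }
                }
            }
            if (!ok) stop("could not sample an index-disjoint negative read");
            seqs[r] = rd;
            origin[r] = 0;
            start[r] = NA_INTEGER;
            revstrand[r] = false;
        }
    }
    return List::create(_["name"] = names, _["sequence"] = seqs, _["origin"] = origin,
                        _["start"] = start, _["reverse"] = revstrand);
}
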
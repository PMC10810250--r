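#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include "kmer.h"

using namespace Rcpp;

// Construction of the colored compacted de Bruijn graph: distinct canonical
// k-mers and their colors, maximal monochromatic unitigs (cut at branches,
// color changes and sentinel reference boundaries), and reference tilings.
// References are split at runs of non-ACGT symbols; each fragment is a
// sentinel-bounded segment of the same reference id.

namespace {

struct KInfo {
    uint32_t color_idx = 0;
    uint8_t degL = 0, degR = 0;
    bool sentL = false, sentR = false;
    int32_t unitig = -1;
    int32_t off = -1;
};

std::string rc_string(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
            case 'A': r[i] = 'T'; break;
            case 'C': r[i] = 'G'; break;
            case 'G': r[i] = 'C'; break;
            case 'T': r[i] = 'A'; break;
        }
    }
    return r;
}

std::vector<std::string> split_fragments(const std::string& s) {
    std::vector<std::string> out;
    std::string cur;
    for (size_t i = 0; i < s.size(); ++i) {
        char c = std::toupper(static_cast<unsigned char>(s[i]));
        if (ccdbg::base2bits(c) >= 0) {
            cur.push_back(c);
        } else if (!cur.empty()) {
            out.push_back(cur);
            cur.clear();
        }
    }
    if (!cur.empty()) out.push_back(cur);
    return out;
}

void check_k(int k) {
    if (k < 3 || k > 31 || k % 2 == 0)
        stop("k must be an odd integer in [3, 31]");
}

} // namespace

// [[Rcpp::export(name = ".canonicalize_cpp")]]
List canonicalize_cpp(CharacterVector kmers) {
    int n = kmers.size();
    CharacterVector canon(n);
    LogicalVector fwd(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        int k = static_cast<int>(s.size());
        if (k < 1 || k > 31) stop("k-mer length must be in [1, 31]");
        uint64_t e;
        if (!ccdbg::encode_kmer(s.c_str(), k, e))
            stop("non-ACGT symbol in k-mer '%s'", s.c_str());
        bool f;
        uint64_t c = ccdbg::canonical_kmer(e, k, f);
        canon[i] = ccdbg::decode_kmer(c, k);
        fwd[i] = f;
    }
    return List::create(_["canonical"] = canon, _["forward"] = fwd);
}

// [[Rcpp::export(name = ".extract_kmer_colors_cpp")]]
List extract_kmer_colors_cpp(CharacterVector seqs, int k) {
    check_k(k);
    if (seqs.size() == 0) stop("empty reference collection");
    std::map<uint64_t, std::vector<uint32_t> > km; // ordered for determinism
    uint64_t mask = (UINT64_C(1) << (2 * k)) - 1;
    for (int i = 0; i < seqs.size(); ++i) {
        std::vector<std::string> frags = split_fragments(as<std::string>(seqs[i]));
        for (size_t fi = 0; fi < frags.size(); ++fi) {
            const std::string& f = frags[fi];
            if (static_cast<int>(f.size()) < k) continue;
            uint64_t e = 0;
            for (int j = 0; j < k - 1; ++j)
                e = (e << 2) | static_cast<uint64_t>(ccdbg::base2bits(f[j]));
            for (size_t p = 0; p + k <= f.size(); ++p) {
                e = ((e << 2) | static_cast<uint64_t>(ccdbg::base2bits(f[p + k - 1]))) & mask;
                bool fw;
                uint64_t c = ccdbg::canonical_kmer(e, k, fw);
                std::vector<uint32_t>& v = km[c];
                if (v.empty() || v.back() != static_cast<uint32_t>(i + 1))
                    v.push_back(static_cast<uint32_t>(i + 1));
            }
        }
    }
    int n = static_cast<int>(km.size());
    CharacterVector kk(n);
    List cols(n);
    int idx = 0;
    for (std::map<uint64_t, std::vector<uint32_t> >::const_iterator it = km.begin();
         it != km.end(); ++it, ++idx) {
        kk[idx] = ccdbg::decode_kmer(it->first, k);
        cols[idx] = IntegerVector(it->second.begin(), it->second.end());
    }
    cols.attr("names") = kk;
    return cols;
}

// [[Rcpp::export(name = ".ccdbg_build_cpp")]]
List ccdbg_build_cpp(CharacterVector seqs, int k) {
    check_k(k);
    int N = seqs.size();
    if (N == 0) stop("empty reference collection");
    uint64_t mask = (UINT64_C(1) << (2 * k)) - 1;

    // fragments per reference
    std::vector<std::vector<std::string> > frags(N);
    for (int i = 0; i < N; ++i)
        frags[i] = split_fragments(as<std::string>(seqs[i]));

    // pass A: k-mer -> color, sentinel flags
    std::unordered_map<uint64_t, KInfo> km;
    std::map<std::vector<uint32_t>, uint32_t> color_dedupe;
    std::vector<std::vector<uint32_t> > prov_colors;
    {
        std::unordered_map<uint64_t, std::vector<uint32_t> > kcol;
        for (int i = 0; i < N; ++i) {
            for (size_t fi = 0; fi < frags[i].size(); ++fi) {
                const std::string& f = frags[i][fi];
                if (static_cast<int>(f.size()) < k) continue;
                uint64_t e = 0;
                for (int j = 0; j < k - 1; ++j)
                    e = (e << 2) | static_cast<uint64_t>(ccdbg::base2bits(f[j]));
                size_t P = f.size() - k + 1;
                for (size_t p = 0; p < P; ++p) {
                    e = ((e << 2) | static_cast<uint64_t>(ccdbg::base2bits(f[p + k - 1]))) & mask;
                    bool fw;
                    uint64_t c = ccdbg::canonical_kmer(e, k, fw);
                    std::vector<uint32_t>& v = kcol[c];
                    if (v.empty() || v.back() != static_cast<uint32_t>(i + 1))
                        v.push_back(static_cast<uint32_t>(i + 1));
                    KInfo& I = km[c];
                    if (p == 0) { if (fw) I.sentL = true; else I.sentR = true; }
                    if (p == P - 1) { if (fw) I.sentR = true; else I.sentL = true; }
                }
            }
        }
        for (std::unordered_map<uint64_t, std::vector<uint32_t> >::iterator it = kcol.begin();
             it != kcol.end(); ++it) {
            std::map<std::vector<uint32_t>, uint32_t>::iterator dit = color_dedupe.find(it->second);
            uint32_t idx;
            if (dit == color_dedupe.end()) {
                idx = static_cast<uint32_t>(prov_colors.size());
                color_dedupe[it->second] = idx;
                prov_colors.push_back(it->second);
            } else {
                idx = dit->second;
            }
            km[it->first].color_idx = idx;
        }
    }
    uint64_t n_kmers = km.size();
    if (n_kmers == 0) {
        // k larger than every reference: empty graph with a warning from R
        return List::create(_["unitigs"] = CharacterVector(0),
                            _["colorIds"] = IntegerVector(0),
                            _["colors"] = List(0),
                            _["tilings"] = List(N),
                            _["n"] = 0.0, _["empty"] = true);
    }

    // pass B: node degrees in canonical orientation
    for (std::unordered_map<uint64_t, KInfo>::iterator it = km.begin(); it != km.end(); ++it) {
        uint64_t c = it->first;
        int dR = 0, dL = 0;
        for (uint64_t b = 0; b < 4; ++b) {
            bool fw;
            uint64_t y = ((c << 2) | b) & mask;
            if (km.count(ccdbg::canonical_kmer(y, k, fw))) ++dR;
            uint64_t z = (b << (2 * (k - 1))) | (c >> 2);
            if (km.count(ccdbg::canonical_kmer(z, k, fw))) ++dL;
        }
        it->second.degR = static_cast<uint8_t>(dR);
        it->second.degL = static_cast<uint8_t>(dL);
    }

    // pass C: walk fragments, cut, collect unitig occurrences and tilings
    std::unordered_map<std::string, uint32_t> unitig_by_spelling;
    std::vector<std::string> spellings;
    std::vector<uint32_t> unitig_color;
    // tilings[i][fi] = vector of (tmp unitig id, occurrence-forward flag)
    std::vector<std::vector<std::vector<std::pair<uint32_t, bool> > > > til(N);

    for (int i = 0; i < N; ++i) {
        til[i].resize(frags[i].size());
        for (size_t fi = 0; fi < frags[i].size(); ++fi) {
            const std::string& f = frags[i][fi];
            if (static_cast<int>(f.size()) < k) continue;
            size_t P = f.size() - k + 1;
            // occurrence encodings and canonical info per position
            std::vector<uint64_t> canon(P);
            std::vector<bool> fwd(P);
            {
                uint64_t e = 0;
                for (int j = 0; j < k - 1; ++j)
                    e = (e << 2) | static_cast<uint64_t>(ccdbg::base2bits(f[j]));
                for (size_t p = 0; p < P; ++p) {
                    e = ((e << 2) | static_cast<uint64_t>(ccdbg::base2bits(f[p + k - 1]))) & mask;
                    bool fw;
                    canon[p] = ccdbg::canonical_kmer(e, k, fw);
                    fwd[p] = fw;
                }
            }
            size_t run_start = 0;
            for (size_t p = 0; p <= P; ++p) {
                bool cut = (p == P);
                if (!cut && p > 0) {
                    const KInfo& I1 = km[canon[p - 1]];
                    const KInfo& I2 = km[canon[p]];
                    bool f1 = fwd[p - 1], f2 = fwd[p];
                    if (canon[p - 1] == canon[p]) cut = true;
                    else if (I1.color_idx != I2.color_idx) cut = true;
                    else if ((f1 ? I1.degR : I1.degL) != 1) cut = true;
                    else if ((f2 ? I2.degL : I2.degR) != 1) cut = true;
                    else if (f1 ? I1.sentR : I1.sentL) cut = true;
                    else if (f2 ? I2.sentL : I2.sentR) cut = true;
                }
                if (!cut) continue;
                if (p > 0 || p == P) {
                    if (p == 0) { run_start = 0; continue; }
                    size_t rs = run_start, re = p - 1; // run = positions [rs, re]
                    run_start = p;
                    size_t L = (re - rs) + k; // spelled length
                    std::string sub = f.substr(rs, L);
                    std::string rcs = rc_string(sub);
                    bool occ_fwd = sub <= rcs;
                    const std::string& spell = occ_fwd ? sub : rcs;
                    uint32_t tid;
                    std::unordered_map<std::string, uint32_t>::iterator uit =
                        unitig_by_spelling.find(spell);
                    bool fresh = (uit == unitig_by_spelling.end());
                    if (fresh) {
                        tid = static_cast<uint32_t>(spellings.size());
                        unitig_by_spelling[spell] = tid;
                        spellings.push_back(spell);
                        unitig_color.push_back(km[canon[rs]].color_idx);
                    } else {
                        tid = uit->second;
                    }
                    // register / verify k-mer placements in canonical coordinates
                    uint32_t col0 = km[canon[rs]].color_idx;
                    for (size_t j = 0; j <= re - rs; ++j) {
                        KInfo& I = km[canon[rs + j]];
                        if (I.color_idx != col0)
                            stop("internal error: non-monochromatic unitig");
                        int32_t off = occ_fwd ? static_cast<int32_t>(j)
                                              : static_cast<int32_t>(L - k - j);
                        if (I.unitig < 0) {
                            I.unitig = static_cast<int32_t>(tid);
                            I.off = off;
                        } else if (I.unitig != static_cast<int32_t>(tid) || I.off != off) {
                            stop("internal error: k-mer assigned to two unitig positions");
                        }
                    }
                    til[i][fi].push_back(std::make_pair(tid, occ_fwd));
                }
            }
        }
    }

    // partition invariant
    uint64_t tot = 0;
    for (size_t t = 0; t < spellings.size(); ++t)
        tot += spellings[t].size() - k + 1;
    if (tot != n_kmers)
        stop("internal error: unitig k-mer partition does not cover the k-mer set");

    // pass D: deterministic color ids (cardinality, then content) and
    // unitig layout (color id, then spelling)
    size_t M = prov_colors.size();
    std::vector<uint32_t> order(M);
    for (size_t j = 0; j < M; ++j) order[j] = static_cast<uint32_t>(j);
    std::sort(order.begin(), order.end(), [&](uint32_t a, uint32_t b) {
        if (prov_colors[a].size() != prov_colors[b].size())
            return prov_colors[a].size() < prov_colors[b].size();
        return prov_colors[a] < prov_colors[b];
    });
    std::vector<uint32_t> color_final(M);
    for (size_t j = 0; j < M; ++j) color_final[order[j]] = static_cast<uint32_t>(j + 1);

    size_t m = spellings.size();
    std::vector<uint32_t> uorder(m);
    for (size_t t = 0; t < m; ++t) uorder[t] = static_cast<uint32_t>(t);
    std::sort(uorder.begin(), uorder.end(), [&](uint32_t a, uint32_t b) {
        uint32_t ca = color_final[unitig_color[a]], cb = color_final[unitig_color[b]];
        if (ca != cb) return ca < cb;
        return spellings[a] < spellings[b];
    });
    std::vector<uint32_t> unitig_final(m);
    for (size_t t = 0; t < m; ++t) unitig_final[uorder[t]] = static_cast<uint32_t>(t + 1);

    CharacterVector unitigs(m);
    IntegerVector color_ids(m);
    for (size_t t = 0; t < m; ++t) {
        unitigs[t] = spellings[uorder[t]];
        color_ids[t] = static_cast<int>(color_final[unitig_color[uorder[t]]]);
    }
    List colors(M);
    for (size_t j = 0; j < M; ++j) {
        const std::vector<uint32_t>& v = prov_colors[order[j]];
        colors[j] = IntegerVector(v.begin(), v.end());
    }
    List tilings(N);
    for (int i = 0; i < N; ++i) {
        List per_frag(til[i].size());
        for (size_t fi = 0; fi < til[i].size(); ++fi) {
            const std::vector<std::pair<uint32_t, bool> >& occ = til[i][fi];
            IntegerMatrix mmat(static_cast<int>(occ.size()), 2);
            for (size_t o = 0; o < occ.size(); ++o) {
                mmat(static_cast<int>(o), 0) = static_cast<int>(unitig_final[occ[o].first]);
                mmat(static_cast<int>(o), 1) = occ[o].second ? 1 : 0;
            }
            colnames(mmat) = CharacterVector::create("unitig", "forward");
            per_frag[fi] = mmat;
        }
        tilings[i] = per_frag;
    }

    return List::create(_["unitigs"] = unitigs,
                        _["colorIds"] = color_ids,
                        _["colors"] = colors,
                        _["tilings"] = tilings,
                        _["n"] = static_cast<double>(n_kmers),
                        _["empty"] = false);
}
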
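#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Exact cross-hybridization scanning of short oligo probes against an
// off-target transcript set. Longest contiguous exact match is found by
// k-mer seed-and-extend: any common substring of length >= k contains a
// shared k-mer, and extending every shared k-mer occurrence to its maximal
// match recovers the true optimum. A primary index at k = 12 covers the
// flagging range cheaply; probes without a 12-mer seed fall back to a k = 6
// index so the reported length is exact down to 6 nt (shorter chance
// matches are irrelevant to any sensible masking threshold and reported as
// the best value found). Ungapped full-probe identity is evaluated at every
// alignment offset implied by a k = 6 seed.

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char complBase(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void buildIndex(const std::string &cat, int k, KmerIndex &idx) {
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    uint64_t code = 0;
    int valid = 0;
    const int n = (int) cat.size();
    for (int i = 0; i < n; ++i) {
        int b = baseCode(cat[(size_t) i]);
        if (b < 0) {
            valid = 0;
            code = 0;
            continue;
        }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid >= k) {
            idx[code].push_back(i - k + 1);
        }
    }
}

struct Catalog {
    std::string cat;           // targets (+ reverse complements), '#'-separated
    std::vector<int> targetOf; // per position: 0-based target index, -1 at '#'
    KmerIndex idx12;
    KmerIndex idx6;
    bool have6;
    Catalog() : have6(false) {}
};

static void buildCatalog(const CharacterVector &targets, bool bothStrands,
                         Catalog &cg) {
    size_t total = 0;
    const int nt = targets.size();
    for (int t = 0; t < nt; ++t) total += LENGTH(STRING_ELT(targets, t)) + 1;
    if (bothStrands) total *= 2;
    cg.cat.reserve(total);
    cg.targetOf.reserve(total);
    for (int pass = 0; pass < (bothStrands ? 2 : 1); ++pass) {
        for (int t = 0; t < nt; ++t) {
            std::string s = as<std::string>(targets[t]);
            if (pass == 1) { // reverse complement
                std::string rc(s.rbegin(), s.rend());
                for (size_t i = 0; i < rc.size(); ++i) rc[i] = complBase(rc[i]);
                s = rc;
            }
            for (size_t i = 0; i < s.size(); ++i) {
                cg.cat.push_back(s[i]);
                cg.targetOf.push_back(t);
            }
            cg.cat.push_back('#');
            cg.targetOf.push_back(-1);
        }
    }
    buildIndex(cg.cat, 12, cg.idx12);
}

// maximal exact match through an aligned pair (probe offset i, catalog pos p)
static int extendMatch(const std::string &probe, int i, const std::string &cat,
                       int p, int seedLen) {
    int l = 0, r = seedLen;
    int pi = i - 1, pp = p - 1;
    while (pi >= 0 && pp >= 0 && cat[(size_t) pp] == probe[(size_t) pi] &&
           baseCode(cat[(size_t) pp]) >= 0) {
        ++l; --pi; --pp;
    }
    int qi = i + seedLen, qp = p + seedLen;
    const int plen = (int) probe.size(), clen = (int) cat.size();
    while (qi < plen && qp < clen && cat[(size_t) qp] == probe[(size_t) qi] &&
           baseCode(cat[(size_t) qp]) >= 0) {
        ++r; ++qi; ++qp;
    }
    return l + r;
}

static void scanSeeds(const std::string &probe, const Catalog &cg,
                      const KmerIndex &idx, int k,
                      int &bestLen, int &bestPartner,
                      double &bestIdent, int &identPartner,
                      std::unordered_set<int> &identStarts,
                      bool doIdentity) {
    const int plen = (int) probe.size();
    const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    uint64_t code = 0;
    int valid = 0;
    for (int i = 0; i < plen; ++i) {
        int b = baseCode(probe[(size_t) i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid < k) continue;
        int off = i - k + 1;
        KmerIndex::const_iterator it = idx.find(code);
        if (it == idx.end()) continue;
        const std::vector<int> &hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
            int p = hits[h];
            int len = extendMatch(probe, off, cg.cat, p, k);
            if (len > bestLen) {
                bestLen = len;
                bestPartner = cg.targetOf[(size_t) p];
            }
            if (doIdentity) {
                int start = p - off;
                if (start >= 0 && start + plen <= (int) cg.cat.size() &&
                    cg.targetOf[(size_t) start] >= 0 &&
                    cg.targetOf[(size_t) start] ==
                        cg.targetOf[(size_t) (start + plen - 1)] &&
                    identStarts.insert(start).second) {
                    int m = 0;
                    for (int j = 0; j < plen; ++j)
                        if (cg.cat[(size_t) (start + j)] == probe[(size_t) j]) ++m;
                    double ident = (double) m / (double) plen;
                    if (ident > bestIdent) {
                        bestIdent = ident;
                        identPartner = cg.targetOf[(size_t) start];
                    }
                }
            }
        }
    }
}

//' @noRd
// [[Rcpp::export(name = ".crossHybScanCpp")]]
List crossHybScanCpp(CharacterVector probes, CharacterVector targets,
                     bool bothStrands = true, bool computeIdentity = true) {
    const int np = probes.size();
    IntegerVector matchLen(np, 0);
    NumericVector identity(np, 0.0);
    IntegerVector partner(np, NA_INTEGER);

    if (targets.size() == 0) {
        return List::create(_["match_len"] = matchLen,
                            _["identity"] = identity,
                            _["partner"] = partner);
    }
    Catalog cg;
    buildCatalog(targets, bothStrands, cg);

    for (int q = 0; q < np; ++q) {
        std::string probe = as<std::string>(probes[q]);
        int bestLen = 0, bestPartner = -1, identPartner = -1;
        double bestIdent = 0.0;
        std::unordered_set<int> identStarts;
        scanSeeds(probe, cg, cg.idx12, 12, bestLen, bestPartner,
                  bestIdent, identPartner, identStarts, false);
        if (bestLen < 12 || computeIdentity) {
            if (!cg.have6) { buildIndex(cg.cat, 6, cg.idx6); cg.have6 = true; }
            scanSeeds(probe, cg, cg.idx6, 6, bestLen, bestPartner,
                      bestIdent, identPartner, identStarts, computeIdentity);
        }
        matchLen[q] = bestLen;
        identity[q] = bestIdent;
        int part = (bestLen > 0) ? bestPartner : identPartner;
        if (part >= 0) partner[q] = part + 1; // 1-based
    }
    return List::create(_["match_len"] = matchLen,
                        _["identity"] = identity,
                        _["partner"] = partner);
}
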
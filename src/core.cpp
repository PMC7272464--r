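#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Hamming distance between two equal-length C strings.
// 'N' (or any non-identical character) counts as a mismatch.
static inline int hamming(const char* a, const char* b, int n, int stop_at) {
    int d = 0;
    for (int i = 0; i < n; ++i) {
        if (a[i] != b[i]) {
            if (++d > stop_at) return d;
        }
    }
    return d;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    if (b.size() != n) stop("vectors must have equal length");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* sa = CHAR(STRING_ELT(a, i));
        const char* sb = CHAR(STRING_ELT(b, i));
        int la = (int) LENGTH(STRING_ELT(a, i));
        int lb = (int) LENGTH(STRING_ELT(b, i));
        if (la != lb) stop("strings must have equal length at position %d", (int)(i + 1));
        out[i] = hamming(sa, sb, la, la);
    }
    return out;
}

// ---- union-find -----------------------------------------------------------

static int uf_find(std::vector<int>& parent, int x) {
    while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
    }
    return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[rb] = ra;
}

// Number of connected components among distinct sequences, edges at
// Hamming distance <= 1.  Sequences must share one length.
static int collapse_components(const std::vector<std::string>& uniq) {
    int m = (int) uniq.size();
    if (m == 0) return 0;
    int len = (int) uniq[0].size();
    std::vector<int> parent(m);
    for (int i = 0; i < m; ++i) parent[i] = i;
    for (int i = 0; i < m; ++i) {
        for (int j = i + 1; j < m; ++j) {
            if (hamming(uniq[i].c_str(), uniq[j].c_str(), len, 1) <= 1)
                uf_union(parent, i, j);
        }
    }
    int comps = 0;
    for (int i = 0; i < m; ++i) if (uf_find(parent, i) == i) ++comps;
    return comps;
}

// [[Rcpp::export]]
int cpp_collapse_umis(CharacterVector umis) {
    R_xlen_t n = umis.size();
    if (n == 0) return 0;
    int len = (int) LENGTH(STRING_ELT(umis, 0));
    std::unordered_map<std::string, int> seen;
    std::vector<std::string> uniq;
    for (R_xlen_t i = 0; i < n; ++i) {
        if ((int) LENGTH(STRING_ELT(umis, i)) != len)
            stop("UMIs of mixed length");
        std::string s = as<std::string>(umis[i]);
        if (seen.find(s) == seen.end()) {
            seen[s] = 1;
            uniq.push_back(s);
        }
    }
    return collapse_components(uniq);
}

// Collapse UMIs within runs of a pre-sorted grouping vector.
// group: integer run ids, non-decreasing; returns one component count per run.
// [[Rcpp::export]]
IntegerVector cpp_collapse_by_group(IntegerVector group, CharacterVector umis) {
    R_xlen_t n = group.size();
    if (umis.size() != n) stop("group/umi length mismatch");
    std::vector<int> counts;
    R_xlen_t i = 0;
    while (i < n) {
        R_xlen_t j = i;
        while (j < n && group[j] == group[i]) ++j;
        std::unordered_map<std::string, int> seen;
        std::vector<std::string> uniq;
        int len = (int) LENGTH(STRING_ELT(umis, i));
        for (R_xlen_t t = i; t < j; ++t) {
            if ((int) LENGTH(STRING_ELT(umis, t)) != len)
                stop("UMIs of mixed length");
            std::string s = as<std::string>(umis[t]);
            if (seen.find(s) == seen.end()) {
                seen[s] = 1;
                uniq.push_back(s);
            }
        }
        counts.push_back(collapse_components(uniq));
        i = j;
    }
    return wrap(counts);
}

// ---- k-mer transcript assignment ------------------------------------------

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

struct Seed { int gene; int pos; };  // 0-based position within transcript

// Assign each read to a gene by seeding k-mers at a few offsets and
// confirming the full read against the transcript window with at most
// max_mm substitutions.  Both orientations are checked.
// Returns: 0-based gene index, -1 unassigned, -2 ambiguous.
// [[Rcpp::export]]
IntegerVector cpp_assign_reads(CharacterVector reads, CharacterVector transcripts,
                               int k, int max_mm, bool check_rc) {
    int n_tx = (int) transcripts.size();
    std::vector<std::string> tx(n_tx);
    std::unordered_map<std::string, std::vector<Seed> > index;
    for (int g = 0; g < n_tx; ++g) {
        tx[g] = as<std::string>(transcripts[g]);
        int L = (int) tx[g].size();
        for (int p = 0; p + k <= L; ++p) {
            index[tx[g].substr(p, k)].push_back({g, p});
        }
    }

    R_xlen_t n = reads.size();
    IntegerVector out(n);
    std::vector<int> hit_gene;  // distinct confirmed genes for current read
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string fwd = as<std::string>(reads[r]);
        int rl = (int) fwd.size();
        hit_gene.clear();
        int n_orient = check_rc ? 2 : 1;
        for (int o = 0; o < n_orient; ++o) {
            std::string rd = (o == 0) ? fwd : revcomp(fwd);
            if (rl < k) continue;
            // seed offsets: start, middle, end of the read
            int offs[3] = {0, (rl - k) / 2, rl - k};
            for (int s = 0; s < 3; ++s) {
                int off = offs[s];
                if (s > 0 && off == offs[s - 1]) continue;
                auto it = index.find(rd.substr(off, k));
                if (it == index.end()) continue;
                for (const Seed& sd : it->second) {
                    int start = sd.pos - off;
                    int L = (int) tx[sd.gene].size();
                    if (start < 0 || start + rl > L) continue;
                    if (hamming(rd.c_str(), tx[sd.gene].c_str() + start, rl, max_mm) <= max_mm) {
                        bool known = false;
                        for (int hg : hit_gene) if (hg == sd.gene) { known = true; break; }
                        if (!known) hit_gene.push_back(sd.gene);
                    }
                }
            }
        }
        if (hit_gene.size() == 0) out[r] = -1;
        else if (hit_gene.size() == 1) out[r] = hit_gene[0];
        else out[r] = -2;
    }
    return out;
}

// Match each observed barcode against a whitelist: exact hit, unique
// Hamming-1 neighbour, or rejection.
// Returns 1-based whitelist index; 0 = no match, -1 = ambiguous.
// [[Rcpp::export]]
IntegerVector cpp_match_barcodes(CharacterVector observed, CharacterVector whitelist) {
    int nw = (int) whitelist.size();
    std::vector<std::string> wl(nw);
    std::unordered_map<std::string, int> exact;
    for (int i = 0; i < nw; ++i) {
        wl[i] = as<std::string>(whitelist[i]);
        exact[wl[i]] = i + 1;
    }
    R_xlen_t n = observed.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string ob = as<std::string>(observed[i]);
        auto it = exact.find(ob);
        if (it != exact.end()) { out[i] = it->second; continue; }
        int hit = 0, nhit = 0;
        for (int w = 0; w < nw; ++w) {
            if (wl[w].size() != ob.size()) continue;
            if (hamming(ob.c_str(), wl[w].c_str(), (int) ob.size(), 1) <= 1) {
                ++nhit;
                hit = w + 1;
                if (nhit > 1) break;
            }
        }
        out[i] = (nhit == 1) ? hit : (nhit == 0 ? 0 : -1);
    }
    return out;
}
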
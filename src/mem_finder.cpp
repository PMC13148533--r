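#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

// Maximal exact match (MEM) enumeration between two sequences via a
// suffix array over their concatenation.
//
// A MEM is a pair of positions (pa, pb) and a length len such that
// a[pa, pa+len) == b[pb, pb+len), and the match can be extended on
// neither side (boundary or mismatch). Right-maximality is automatic
// because len is the full longest common prefix of the two suffixes;
// left-maximality is checked on the preceding characters.
//
// The caller is expected to mask ambiguous symbols to characters that
// can never compare equal across the two sequences (e.g. 'X' in a and
// 'Y' in b), which realises "non-ACGT is a universal mismatch".

namespace {

// Suffix array by rank doubling over packed 64-bit (rank, next-rank) keys
// (O(n log^2 n) worst case, but random genomic text resolves in a few
// rounds); n here is modest (desk-scale genomes), so this beats the
// complexity of SA-IS.
std::vector<int> build_suffix_array(const std::string &s) {
    const int n = static_cast<int>(s.size());
    std::vector<int> sa(n), rank_(n);
    std::vector<uint64_t> key(n);
    for (int i = 0; i < n; ++i) {
        sa[i] = i;
        rank_[i] = static_cast<unsigned char>(s[i]);
    }
    for (int k = 1;; k <<= 1) {
        for (int i = 0; i < n; ++i)
            key[i] = (static_cast<uint64_t>(rank_[i]) << 32) |
                     static_cast<uint32_t>(i + k < n ? rank_[i + k] + 1 : 0);
        std::sort(sa.begin(), sa.end(),
                  [&](int a, int b) { return key[a] < key[b]; });
        rank_[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            rank_[sa[i]] = rank_[sa[i - 1]] + (key[sa[i]] != key[sa[i - 1]]);
        if (rank_[sa[n - 1]] == n - 1) break;
    }
    return sa;
}

// Kasai's algorithm: lcp[i] = LCP(suffix sa[i-1], suffix sa[i]), lcp[0] = 0.
std::vector<int> build_lcp(const std::string &s, const std::vector<int> &sa) {
    const int n = static_cast<int>(s.size());
    std::vector<int> rank_(n), lcp(n, 0);
    for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rank_[i] > 0) {
            int j = sa[rank_[i] - 1];
            while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
            lcp[rank_[i]] = h;
            if (h > 0) --h;
        } else {
            h = 0;
        }
    }
    return lcp;
}

} // namespace

// [[Rcpp::export(name = ".memFinderCpp")]]
Rcpp::DataFrame memFinderCpp(const std::string &a, const std::string &b,
                             const int min_len) {
    if (min_len < 2) Rcpp::stop("min_len must be >= 2");
    if (a.empty() || b.empty()) Rcpp::stop("sequences must be non-empty");

    // '\x01' separates the sequences; it occurs nowhere else, so no
    // common prefix can cross it.
    std::string s = a;
    s.push_back('\x01');
    s += b;
    const int na = static_cast<int>(a.size());
    const int n = static_cast<int>(s.size());

    std::vector<int> sa = build_suffix_array(s);
    std::vector<int> lcp = build_lcp(s, sa);

    std::vector<int> out_a, out_b, out_len;

    // Maximal runs of suffix-array slots whose consecutive LCP >= min_len:
    // every pair inside a run shares a prefix of >= min_len, and the pair's
    // exact LCP is the running minimum of consecutive LCPs between them.
    int run_start = 0;
    for (int i = 1; i <= n; ++i) {
        const bool joined = (i < n) && (lcp[i] >= min_len);
        if (!joined) {
            const int run_end = i - 1; // inclusive
            if (run_end > run_start) {
                for (int p = run_start; p < run_end; ++p) {
                    int cur = INT_MAX;
                    for (int q = p + 1; q <= run_end; ++q) {
                        cur = std::min(cur, lcp[q]);
                        const int sp = sa[p], sq = sa[q];
                        const bool p_in_a = sp < na;
                        const bool q_in_a = sq < na;
                        if (p_in_a == q_in_a) continue; // need one from each
                        const int pa = p_in_a ? sp : sq;
                        const int pb = (p_in_a ? sq : sp) - na - 1;
                        // left-maximality: boundary or differing previous char
                        if (pa > 0 && pb > 0 && a[pa - 1] == b[pb - 1]) continue;
                        out_a.push_back(pa);
                        out_b.push_back(pb);
                        out_len.push_back(cur);
                    }
                }
            }
            run_start = i;
        }
    }

    return Rcpp::DataFrame::create(
        Rcpp::Named("start_a") = out_a,
        Rcpp::Named("start_b") = out_b,
        Rcpp::Named("length") = out_len);
}
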
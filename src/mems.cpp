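#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Suffix array by prefix doubling with counting sort, O(n log n).
// Codes must be >= 1; a 0 sentinel is appended internally by the caller.
static void suffix_array(const std::vector<int>& s, std::vector<int>& sa) {
    const int n = (int) s.size();
    sa.assign(n, 0);
    if (n == 0) return;
    std::vector<int> r(n), tmp(n);
    int maxv = 0;
    for (int v : s) maxv = std::max(maxv, v);
    std::vector<int> cnt(std::max(maxv + 2, n + 1), 0);

    for (int i = 0; i < n; ++i) cnt[s[i] + 1]++;
    for (int i = 1; i <= maxv + 1; ++i) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; ++i) sa[cnt[s[i]]++] = i;
    r[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
        r[sa[i]] = r[sa[i - 1]] + (s[sa[i]] != s[sa[i - 1]] ? 1 : 0);

    for (int k = 1; k < n; k <<= 1) {
        if (r[sa[n - 1]] == n - 1) break;  // all ranks distinct
        // order by second key: suffixes with i+k >= n first, then sa shifted
        int idx = 0;
        for (int i = n - k; i < n; ++i) tmp[idx++] = i;
        for (int i = 0; i < n; ++i)
            if (sa[i] >= k) tmp[idx++] = sa[i] - k;
        // stable counting sort by first key r
        std::fill(cnt.begin(), cnt.begin() + n + 1, 0);
        for (int i = 0; i < n; ++i) cnt[r[i] + 1]++;
        for (int i = 1; i <= n; ++i) cnt[i] += cnt[i - 1];
        for (int i = 0; i < n; ++i) sa[cnt[r[tmp[i]]]++] = tmp[i];
        // recompute ranks
        std::vector<int> r2(n);
        r2[sa[0]] = 0;
        for (int i = 1; i < n; ++i) {
            int a = sa[i - 1], b = sa[i];
            bool diff = r[a] != r[b];
            if (!diff) {
                int ra = (a + k < n) ? r[a + k] : -1;
                int rb = (b + k < n) ? r[b + k] : -1;
                diff = (ra != rb);
            }
            r2[b] = r2[a] + (diff ? 1 : 0);
        }
        r.swap(r2);
    }
}

// Kasai's LCP: lcp[i] = lcp(suffix sa[i-1], suffix sa[i]), lcp[0] = 0.
static void kasai(const std::vector<int>& s, const std::vector<int>& sa,
                  std::vector<int>& lcp) {
    const int n = (int) s.size();
    lcp.assign(n, 0);
    std::vector<int> rank_(n);
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
}

// Enumerate left- and right-maximal suffix pairs with LCP >= minlen.
//
// codes: encoded concatenation; ACGT are 1..4, every N and every separator
//   carries a unique code >= 5, so ambiguous bases match nothing (not even
//   another N) and no match crosses a record boundary.
// owner: record index per position (any value on never-matching positions).
// mode:  0 = pair   (matches between owner 0 and owner 1, A-position first)
//        1 = self   (all pairs within one record, pos_a < pos_b)
//        2 = cross  (pairs with different owners; used by the uniqueness
//                    filter; reports owner ids alongside positions)
// [[Rcpp::export(name = ".mem_enumerate")]]
List mem_enumerate(IntegerVector codes, IntegerVector owner, int minlen,
                   int mode) {
    const int n0 = codes.size();
    std::vector<int> s(n0 + 1);
    for (int i = 0; i < n0; ++i) {
        if (codes[i] < 1) stop("internal: codes must be >= 1");
        s[i] = codes[i];
    }
    s[n0] = 0;  // sentinel
    const int n = n0 + 1;

    std::vector<int> sa, lcp;
    suffix_array(s, sa);
    kasai(s, sa, lcp);

    std::vector<int> out_a, out_b, out_len, own_a, own_b;

    int i = 1;
    while (i < n) {
        if (lcp[i] < minlen) { ++i; continue; }
        int l = i - 1;            // block of suffixes sa[l..r]
        int r = i;
        while (r + 1 < n && lcp[r + 1] >= minlen) ++r;
        for (int ii = l; ii < r; ++ii) {
            int m = INT_MAX;
            for (int jj = ii + 1; jj <= r; ++jj) {
                m = std::min(m, lcp[jj]);   // running min = pair LCP
                int pa = sa[ii], pb = sa[jj];
                // left-maximality: boundary or differing preceding symbols
                if (pa > 0 && pb > 0 && s[pa - 1] == s[pb - 1]) continue;
                int oa = owner[pa], ob = owner[pb];
                if (mode == 0) {
                    if (oa == ob) continue;
                    if (oa > ob) { std::swap(pa, pb); std::swap(oa, ob); }
                } else if (mode == 1) {
                    if (pa > pb) std::swap(pa, pb);
                } else {
                    if (oa == ob) continue;
                    if (oa > ob) { std::swap(pa, pb); std::swap(oa, ob); }
                }
                out_a.push_back(pa);
                out_b.push_back(pb);
                out_len.push_back(m);
                if (mode == 2) { own_a.push_back(oa); own_b.push_back(ob); }
            }
        }
        i = r + 1;
    }

    if (mode == 2)
        return List::create(_["pos_a"] = out_a, _["pos_b"] = out_b,
                            _["length"] = out_len,
                            _["owner_a"] = own_a, _["owner_b"] = own_b);
    return List::create(_["pos_a"] = out_a, _["pos_b"] = out_b,
                        _["length"] = out_len);
}
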
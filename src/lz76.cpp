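#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Exhaustive LZ76 factorization.
//
// Each factor is the shortest prefix of the unscanned remainder that does
// not occur as a substring of the text truncated one symbol before the
// factor's end; equivalently, a factor starting at i has length
// LPF[i] + 1, where LPF[i] is the length of the longest prefix of the
// suffix s[i..] that also occurs starting at some earlier position p < i
// (the earlier occurrence may run past i, i.e. self-overlap is allowed).
// The trailing factor may remain reproducible.
//
// LPF is computed from the suffix array + LCP array with the linked-list
// deletion scheme: positions are removed in decreasing text order, so when
// position i is processed its list neighbours are the lexicographically
// nearest suffixes starting strictly before i, and pairwise LCPs are
// maintained by taking minima on deletion.  Overall O(n log n).

namespace {

// suffix array by prefix doubling with counting sort; codes must be >= 1
std::vector<int> build_sa(const std::vector<int>& str) {
    std::vector<int> s(str);
    s.push_back(0); // sentinel, strictly smaller than every code
    const int n = static_cast<int>(s.size());
    const int alpha = *std::max_element(s.begin(), s.end()) + 1;

    std::vector<int> p(n), c(n), pn(n), cn(n);
    std::vector<int> cnt(std::max(alpha, n), 0);

    for (int i = 0; i < n; ++i) cnt[s[i]]++;
    for (int i = 1; i < alpha; ++i) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; ++i) p[--cnt[s[i]]] = i;
    c[p[0]] = 0;
    int classes = 1;
    for (int i = 1; i < n; ++i) {
        if (s[p[i]] != s[p[i - 1]]) ++classes;
        c[p[i]] = classes - 1;
    }

    for (int h = 0; (1 << h) < n; ++h) {
        const int k = 1 << h;
        for (int i = 0; i < n; ++i) {
            pn[i] = p[i] - k;
            if (pn[i] < 0) pn[i] += n;
        }
        std::fill(cnt.begin(), cnt.begin() + classes, 0);
        for (int i = 0; i < n; ++i) cnt[c[pn[i]]]++;
        for (int i = 1; i < classes; ++i) cnt[i] += cnt[i - 1];
        for (int i = n - 1; i >= 0; --i) p[--cnt[c[pn[i]]]] = pn[i];
        cn[p[0]] = 0;
        classes = 1;
        for (int i = 1; i < n; ++i) {
            int cur1 = c[p[i]],     cur2 = c[(p[i] + k) % n];
            int prev1 = c[p[i - 1]], prev2 = c[(p[i - 1] + k) % n];
            if (cur1 != prev1 || cur2 != prev2) ++classes;
            cn[p[i]] = classes - 1;
        }
        c.swap(cn);
        if (classes == n) break;
    }
    // drop the sentinel suffix (rank 0)
    return std::vector<int>(p.begin() + 1, p.end());
}

// Kasai LCP: lcp[r] = LCP(sa[r-1], sa[r]), lcp[0] = 0
std::vector<int> build_lcp(const std::vector<int>& s, const std::vector<int>& sa) {
    const int n = static_cast<int>(s.size());
    std::vector<int> rank_(n), lcp(n, 0);
    for (int r = 0; r < n; ++r) rank_[sa[r]] = r;
    int k = 0;
    for (int i = 0; i < n; ++i) {
        if (rank_[i] == 0) { k = 0; continue; }
        int j = sa[rank_[i] - 1];
        while (i + k < n && j + k < n && s[i + k] == s[j + k]) ++k;
        lcp[rank_[i]] = k;
        if (k > 0) --k;
    }
    return lcp;
}

std::vector<int> build_lpf(const std::vector<int>& s) {
    const int n = static_cast<int>(s.size());
    std::vector<int> lpf(n, 0);
    if (n == 0) return lpf;
    std::vector<int> sa = build_sa(s);
    std::vector<int> lcp = build_lcp(s, sa);
    std::vector<int> rank_(n);
    for (int r = 0; r < n; ++r) rank_[sa[r]] = r;

    // doubly linked list over suffix-array ranks; lcpv[r] = LCP between
    // rank r and its current previous live neighbour
    std::vector<int> prev(n), next(n), lcpv(lcp);
    for (int r = 0; r < n; ++r) { prev[r] = r - 1; next[r] = r + 1; }

    for (int i = n - 1; i >= 0; --i) {
        const int r = rank_[i];
        const int up = lcpv[r];
        const int dn = (next[r] < n) ? lcpv[next[r]] : 0;
        lpf[i] = std::max(up, dn);
        if (next[r] < n) lcpv[next[r]] = std::min(up, dn);
        if (prev[r] >= 0) next[prev[r]] = next[r];
        if (next[r] < n) prev[next[r]] = prev[r];
    }
    return lpf;
}

} // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector lz76_factor_ends(Rcpp::IntegerVector codes) {
    const int n = codes.size();
    if (n == 0) return Rcpp::IntegerVector(0);
    std::vector<int> s(codes.begin(), codes.end());
    for (int i = 0; i < n; ++i) {
        if (s[i] < 1) Rcpp::stop("symbol codes must be positive integers");
    }
    std::vector<int> lpf = build_lpf(s);
    std::vector<int> ends;
    int i = 0;
    while (i < n) {
        int len = std::min(lpf[i] + 1, n - i);
        i += len;
        ends.push_back(i); // 0-based half-open end == 1-based inclusive end
    }
    return Rcpp::wrap(ends);
}

// [[Rcpp::export]]
Rcpp::IntegerVector lz76_lpf(Rcpp::IntegerVector codes) {
    std::vector<int> s(codes.begin(), codes.end());
    return Rcpp::wrap(build_lpf(s));
}
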
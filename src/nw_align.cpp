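#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with a linear gap penalty.
// End gaps are penalised, so the alignment always spans both sequences.
// Traceback preference on score ties is diagonal > up > left, which makes
// the reported alignment deterministic for a given input order; callers
// that need symmetry canonicalise the pair before calling.
//
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
    const int n = a.size(), m = b.size();
    // score matrix, row-major (n+1) x (m+1)
    std::vector<double> S((n + 1) * (m + 1));
    for (int j = 0; j <= m; ++j) S[j] = gap * j;
    for (int i = 1; i <= n; ++i) {
        S[i * (m + 1)] = gap * i;
        const char ai = a[i - 1];
        const double* prev = &S[(i - 1) * (m + 1)];
        double* cur = &S[i * (m + 1)];
        for (int j = 1; j <= m; ++j) {
            double diag = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
            double up = prev[j] + gap;
            double left = cur[j - 1] + gap;
            double best = diag;
            if (up > best) best = up;
            if (left > best) best = left;
            cur[j] = best;
        }
    }
    // traceback
    std::string pa, pb;
    pa.reserve(n + m);
    pb.reserve(n + m);
    int i = n, j = m;
    const double eps = 1e-9;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0) {
            double sub = (a[i - 1] == b[j - 1] ? match : mismatch);
            if (std::abs(S[i * (m + 1) + j] - (S[(i - 1) * (m + 1) + j - 1] + sub)) < eps) {
                pa.push_back(a[i - 1]);
                pb.push_back(b[j - 1]);
                --i; --j;
                continue;
            }
        }
        if (i > 0 && std::abs(S[i * (m + 1) + j] - (S[(i - 1) * (m + 1) + j] + gap)) < eps) {
            pa.push_back(a[i - 1]);
            pb.push_back('-');
            --i;
        } else {
            pa.push_back('-');
            pb.push_back(b[j - 1]);
            --j;
        }
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());

    const int len = pa.size();
    int matches = 0;
    for (int k = 0; k < len; ++k)
        if (pa[k] == pb[k] && pa[k] != '-') ++matches;

    // span of columns after stripping terminal (leading/trailing) gap runs
    int lo = 0, hi = len - 1;
    while (lo < len && (pa[lo] == '-' || pb[lo] == '-')) ++lo;
    while (hi >= 0 && (pa[hi] == '-' || pb[hi] == '-')) --hi;
    int core_len = 0, core_matches = 0;
    for (int k = lo; k <= hi; ++k) {
        ++core_len;
        if (pa[k] == pb[k] && pa[k] != '-') ++core_matches;
    }

    return List::create(
        _["score"] = S[n * (m + 1) + m],
        _["length"] = len,
        _["matches"] = matches,
        _["core_length"] = core_len,
        _["core_matches"] = core_matches,
        _["aligned_a"] = pa,
        _["aligned_b"] = pb);
}
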
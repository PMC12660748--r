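#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Minimal period of x[0..m) via the KMP border array: m - border(m).
// For a tandem run this equals the run's generating period iff the reported
// period is primitive.
static int minimal_period(const char *x, int m) {
    std::vector<int> f(m + 1, 0);
    int k = 0;
    for (int i = 1; i < m; ++i) {
        while (k > 0 && x[i] != x[k]) k = f[k];
        if (x[i] == x[k]) ++k;
        f[i + 1] = k;
    }
    return m - f[m];
}

// Scan one sequence for all maximal perfect tandem arrays with primitive
// period in [1, max_period] and at least min_copies complete unit copies.
// 'N' matches nothing (not even itself), so arrays never cross an N.
// Coordinates returned 0-based half-open.
// [[Rcpp::export]]
DataFrame scan_tandem_arrays(std::string seq, int max_period, int min_copies) {
    const char *s = seq.c_str();
    const int n = (int)seq.size();
    std::vector<int> out_start, out_end, out_period;

    for (int p = 1; p <= max_period && 2 * p <= n; ++p) {
        const int limit = n - p;   // match positions t in [0, limit)
        int run_start = -1;
        for (int i = 0; i <= limit; ++i) {
            bool m = (i < limit) && s[i] != 'N' && s[i + p] != 'N' &&
                     s[i] == s[i + p];
            if (m) {
                if (run_start < 0) run_start = i;
            } else if (run_start >= 0) {
                const int L = i - run_start;     // matches [run_start, i)
                const int span = L + p;          // array [run_start, run_start+span)
                if (L >= p && span / p >= min_copies) {
                    // keep only the primitive reading of each run
                    if (minimal_period(s + run_start, span) == p) {
                        out_start.push_back(run_start);
                        out_end.push_back(run_start + span);
                        out_period.push_back(p);
                    }
                }
                run_start = -1;
            }
        }
    }
    return DataFrame::create(_["start"] = out_start,
                             _["end"] = out_end,
                             _["period"] = out_period);
}

// Length of the longest common subsequence of a and b: the maximal number of
// matched positions in a global alignment scoring match=1, mismatch/indel=0.
static int lcs_len(const std::string &a, const std::string &b) {
    const int la = (int)a.size(), lb = (int)b.size();
    std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
    for (int i = 1; i <= la; ++i) {
        for (int j = 1; j <= lb; ++j) {
            if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
            else cur[j] = std::max(prev[j], cur[j - 1]);
        }
        std::swap(prev, cur);
    }
    return prev[lb];
}

static std::string revcomp(const std::string &x) {
    std::string r(x.rbegin(), x.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

//' Phase- and strand-insensitive alignment identity of two repeat units
//'
//' Identity is the maximal number of matched positions in a global alignment
//' (match 1, mismatch/indel 0) divided by the longer unit length, maximised
//' over every cyclic rotation of the second unit and of its reverse
//' complement. Tandem-repeat units have arbitrary phase and strand, so two
//' units describing the same repeat always score 1.
//'
//' @param a,b Repeat unit strings (uppercase DNA).
//' @return Identity fraction in \[0,1\].
//' @examples
//' unit_identity("ACGTACGTACGT", "GTACGTACGTAC")  # rotation: 1
//' unit_identity("AAAAAAAAA", "CCCCCCCCC")        # disjoint: 0
//' @export
// [[Rcpp::export]]
double unit_identity(std::string a, std::string b) {
    const int la = (int)a.size(), lb = (int)b.size();
    if (la == 0 || lb == 0) return 0.0;
    const double denom = (double)std::max(la, lb);
    int best = 0;
    std::string rb = revcomp(b);
    for (int phase = 0; phase < lb; ++phase) {
        std::string rot = b.substr(phase) + b.substr(0, phase);
        best = std::max(best, lcs_len(a, rot));
        std::string rotc = rb.substr(phase) + rb.substr(0, phase);
        best = std::max(best, lcs_len(a, rotc));
        if (best == std::min(la, lb)) break;  // cannot improve
    }
    return best / denom;
}
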
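#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Tie-break during traceback construction: diagonal > up > left.
// Sequences arrive as integer codes; only equality matters.
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b,
                  double match, double mismatch, double gap) {
    const int n = a.size(), m = b.size();
    NumericMatrix S(n + 1, m + 1);
    IntegerMatrix T(n + 1, m + 1); // 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
    for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; T(i, 0) = 1; }
    for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; T(0, j) = 2; }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
            const double u = S(i - 1, j) + gap;
            const double l = S(i, j - 1) + gap;
            if (d >= u && d >= l)      { S(i, j) = d; T(i, j) = 0; }
            else if (u >= l)           { S(i, j) = u; T(i, j) = 1; }
            else                       { S(i, j) = l; T(i, j) = 2; }
        }
    }
    int i = n, j = m, ident = 0, len = 0;
    while (i > 0 || j > 0) {
        const int t = (i == 0) ? 2 : (j == 0) ? 1 : T(i, j);
        if (t == 0)      { if (a[i - 1] == b[j - 1]) ++ident; --i; --j; }
        else if (t == 1) { --i; }
        else             { --j; }
        ++len;
    }
    return List::create(_["score"] = S(n, m),
                        _["identities"] = ident,
                        _["aligned_length"] = len);
}
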
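#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Gotoh three-state global alignment with affine gaps.
// Convention: a gap run of length L costs gap_open + L * gap_extend
// (open charged once per run, extension charged for every gapped base,
// including the first). End gaps are penalised (true global alignment).
// 'N' never matches anything, itself included; it always scores `mismatch`.

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
double align_affine_cpp(std::string a, std::string b,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const double NEG = -std::numeric_limits<double>::infinity();

  // Rolling rows over j; M = both consumed, X = gap in b (a consumed),
  // Y = gap in a (b consumed).
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);

  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG;
    Xp[j] = NEG;
    Yp[j] = gap_open + j * gap_extend;
  }

  for (int i = 1; i <= n; ++i) {
    M[0] = NEG;
    X[0] = gap_open + i * gap_extend;
    Y[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      M[j] = std::max({Mp[j - 1], Xp[j - 1], Yp[j - 1]}) + s;
      X[j] = std::max({Mp[j] + gap_open + gap_extend,
                       Xp[j] + gap_extend,
                       Yp[j] + gap_open + gap_extend});
      Y[j] = std::max({M[j - 1] + gap_open + gap_extend,
                       Y[j - 1] + gap_extend,
                       X[j - 1] + gap_open + gap_extend});
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return std::max({Mp[m], Xp[m], Yp[m]});
}
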
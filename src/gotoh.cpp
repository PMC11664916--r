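// Global pairwise alignment with affine gaps (Gotoh), used by the
// sequence funnel for identity computation and residue-position mapping.
// A gap of length L costs open + ext * L; end gaps are penalised
// (true global alignment). Traceback prefers diagonal, then a gap in
// the second sequence, then a gap in the first, which keeps results
// deterministic.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// a, b: 0-based indices into the scoring matrix alphabet.
// Returns score plus aligned index vectors (1-based; 0 marks a gap).
// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gapOpen, double gapExt) {
  const int n = a.size(), m = b.size();
  const double go = gapOpen + gapExt;  // cost of opening a length-1 gap
  // state matrices: H best, X gap-in-b (consumes a), Y gap-in-a
  std::vector<double> H((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // traceback: 0 = diag, 1 = up (X), 2 = left (Y); per state, whether the
  // gap was extended (stay) or opened (come from H)
  std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0),
      extX((n + 1) * (m + 1), 0), extY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  H[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gapOpen + gapExt * i);
    H[at(i, 0)] = X[at(i, 0)];
    ptrH[at(i, 0)] = 1;
    extX[at(i, 0)] = (i > 1);
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gapOpen + gapExt * j);
    H[at(0, j)] = Y[at(0, j)];
    ptrH[at(0, j)] = 2;
    extY[at(0, j)] = (j > 1);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double xOpen = H[at(i - 1, j)] - go;
      double xExt = X[at(i - 1, j)] - gapExt;
      if (xExt > xOpen) { X[at(i, j)] = xExt; extX[at(i, j)] = 1; }
      else { X[at(i, j)] = xOpen; extX[at(i, j)] = 0; }

      double yOpen = H[at(i, j - 1)] - go;
      double yExt = Y[at(i, j - 1)] - gapExt;
      if (yExt > yOpen) { Y[at(i, j)] = yExt; extY[at(i, j)] = 1; }
      else { Y[at(i, j)] = yOpen; extY[at(i, j)] = 0; }

      double diag = H[at(i - 1, j - 1)] + S(a[i - 1], b[j - 1]);
      double best = diag;
      unsigned char p = 0;
      if (X[at(i, j)] > best) { best = X[at(i, j)]; p = 1; }
      if (Y[at(i, j)] > best) { best = Y[at(i, j)]; p = 2; }
      H[at(i, j)] = best;
      ptrH[at(i, j)] = p;
    }
  }

  // traceback
  std::vector<int> ai, bi;
  ai.reserve(n + m);
  bi.reserve(n + m);
  int i = n, j = m;
  int state = ptrH[at(i, j)];  // 0 H-diag, 1 X, 2 Y
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      if (i > 0 || j > 0) state = ptrH[at(i, j)];
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      bool wasExt = extX[at(i, j)];
      --i;
      state = wasExt ? 1 : ((i > 0 || j > 0) ? ptrH[at(i, j)] : 0);
    } else {
      ai.push_back(0); bi.push_back(j);
      bool wasExt = extY[at(i, j)];
      --j;
      state = wasExt ? 2 : ((i > 0 || j > 0) ? ptrH[at(i, j)] : 0);
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = H[at(n, m)],
                      _["a_index"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_index"] = IntegerVector(bi.begin(), bi.end()));
}
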
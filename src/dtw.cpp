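// Dynamic time warping with absolute-difference local cost and symmetric
// unit steps {(1,1), (1,0), (0,1)}. No warping-window constraint. The
// backtrace prefers the diagonal step on cost ties so that identical series
// return the identity (diagonal) path.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_dtw(const NumericVector& a, const NumericVector& b) {
  const int n = a.size(), m = b.size();
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 = diag, 1 = up (i-1,j), 2 = left (i,j-1)
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(a[i] - b[j]);
      if (i == 0 && j == 0) {
        D(i, j) = c;
        from(i, j) = -1;
      } else if (i == 0) {
        D(i, j) = c + D(i, j - 1);
        from(i, j) = 2;
      } else if (j == 0) {
        D(i, j) = c + D(i - 1, j);
        from(i, j) = 1;
      } else {
        double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
        double best = dd;
        int arg = 0;
        if (du < best) { best = du; arg = 1; }
        if (dl < best) { best = dl; arg = 2; }
        D(i, j) = c + best;
        from(i, j) = arg;
      }
    }
  }
  // backtrace
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (i >= 0 && j >= 0) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    int f = from(i, j);
    if (f == -1) break;
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(Named("path") = path, Named("cost") = D(n - 1, m - 1));
}
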
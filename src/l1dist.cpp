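#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pairwise Manhattan (L1) distance between the rows of X.
// Returns the full symmetric n x n matrix; the silhouette machinery
// indexes rows and columns by cell, so the dense form is what we want.
// X is copied into a row-contiguous buffer first: the inner loop then
// streams both profiles sequentially, which is what makes this fast.
// [[Rcpp::export(name = ".l1_dist_cpp")]]
NumericMatrix l1_dist_cpp(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xt((size_t)n * p);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i)
      xt[(size_t)i * p + k] = X[i + (R_xlen_t)n * k];
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    const double *xi = &xt[(size_t)i * p];
    for (int j = i + 1; j < n; ++j) {
      const double *xj = &xt[(size_t)j * p];
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = xi[k] - xj[k];
        s += d < 0 ? -d : d;
      }
      D(i, j) = s;
      D(j, i) = s;
    }
  }
  return D;
}
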
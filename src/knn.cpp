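#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Inverse-square-distance weighted kNN vote from a query x train matrix of
// squared distances. labels are 1-based class indices; ties in the summed
// vote break to the smallest class index (callers order class levels
// lexicographically, making the tie-break lexicographic and deterministic).
// [[Rcpp::export]]
IntegerVector cpp_wknn_vote(const NumericMatrix& D2, const IntegerVector& labels,
                            int k, int n_classes, double eps = 1e-12) {
  const int nq = D2.nrow(), nt = D2.ncol();
  const double eps2 = eps * eps;
  IntegerVector pred(nq);
  std::vector<int> idx(nt);
  std::vector<double> votes(n_classes);

  for (int q = 0; q < nq; ++q) {
    for (int j = 0; j < nt; ++j) idx[j] = j;
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) {
                        if (D2(q, a) != D2(q, b)) return D2(q, a) < D2(q, b);
                        return a < b;
                      });
    std::fill(votes.begin(), votes.end(), 0.0);
    for (int j = 0; j < k; ++j) {
      double d2 = std::max(D2(q, idx[j]), eps2);
      votes[labels[idx[j]] - 1] += 1.0 / d2;
    }
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[c] > votes[best]) best = c;
    pred[q] = best + 1;
  }
  return pred;
}
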
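#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
using namespace Rcpp;

// Exact k-nearest neighbours under squared Euclidean distance.
// Ties are broken by the smaller row index so results are deterministic.
// Returns an n x k matrix of 1-based neighbour indices, nearest first.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be smaller than the number of events");
  // row-major copy for contiguous access in the inner loop
  std::vector<double> Xr((size_t)n * d);
  for (int p = 0; p < n; ++p)
    for (int j = 0; j < d; ++j) Xr[(size_t)p * d + j] = X(p, j);

  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    for (int p = 0; p < n; ++p) {
      const double* xp = &Xr[(size_t)p * d];
      double s = 0.0;
      for (int j = 0; j < d; ++j) { double t = xp[j] - xi[j]; s += t * t; }
      cand[p] = std::make_pair(s, p);
    }
    cand[i].first = R_PosInf;  // a point is never its own neighbour
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Convert directed k-NN lists to an undirected edge set weighted by the
// Jaccard coefficient of the endpoints' neighbour sets.  Edges with zero
// Jaccard overlap are dropped; each surviving edge is stored once (from < to).
// [[Rcpp::export]]
DataFrame cpp_jaccard_edges(IntegerMatrix nn) {
  const int n = nn.nrow(), k = nn.ncol();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    nb[i].resize(k);
    for (int j = 0; j < k; ++j) nb[i][j] = nn(i, j) - 1;
    std::sort(nb[i].begin(), nb[i].end());
  }
  std::vector<std::pair<int, int> > pairs;
  pairs.reserve((size_t)n * k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) {
      int v = nb[i][j];
      if (i == v) continue;
      if (i < v) pairs.push_back(std::make_pair(i, v));
      else pairs.push_back(std::make_pair(v, i));
    }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());

  std::vector<int> from, to;
  std::vector<double> w;
  from.reserve(pairs.size()); to.reserve(pairs.size()); w.reserve(pairs.size());
  for (size_t e = 0; e < pairs.size(); ++e) {
    const std::vector<int>& A = nb[pairs[e].first];
    const std::vector<int>& B = nb[pairs[e].second];
    int ia = 0, ib = 0, inter = 0;
    while (ia < k && ib < k) {
      if (A[ia] < B[ib]) ++ia;
      else if (A[ia] > B[ib]) ++ib;
      else { ++inter; ++ia; ++ib; }
    }
    if (inter == 0) continue;  // prune zero-overlap edges
    from.push_back(pairs[e].first + 1);
    to.push_back(pairs[e].second + 1);
    w.push_back((double)inter / (double)(2 * k - inter));
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["weight"] = w);
}
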